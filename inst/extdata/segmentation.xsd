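<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">
  <xs:complexType name="valueElem">
    <xs:attribute name="value" type="xs:string" use="required"/>
  </xs:complexType>
  <xs:complexType name="pointElem">
    <xs:attribute name="x" type="xs:double" use="required"/>
    <xs:attribute name="y" type="xs:double" use="required"/>
  </xs:complexType>
  <xs:element name="workset">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="description">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="RVpeak" type="valueElem" minOccurs="0"/>
              <xs:element name="LVpeak" type="valueElem" minOccurs="0"/>
              <xs:element name="RVinsertion" type="valueElem" minOccurs="0"/>
              <xs:element name="slice" type="valueElem" minOccurs="0"/>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="frame" minOccurs="0" maxOccurs="unbounded">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="star">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="center" type="pointElem"/>
                    <xs:element name="point" type="pointElem" minOccurs="3" maxOccurs="3"/>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
              <xs:element name="section" minOccurs="2" maxOccurs="2">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="point" type="pointElem" minOccurs="3" maxOccurs="unbounded"/>
                  </xs:sequence>
                  <xs:attribute name="role" use="required">
                    <xs:simpleType>
                      <xs:restriction base="xs:string">
                        <xs:enumeration value="endocardium"/>
                        <xs:enumeration value="epicardium"/>
                      </xs:restriction>
                    </xs:simpleType>
                  </xs:attribute>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
            <xs:attribute name="image" type="xs:string" use="required"/>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
    </xs:complexType>
  </xs:element>
</xs:schema>
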