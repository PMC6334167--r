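<?xml version="1.0" encoding="UTF-8"?>
<!-- Minimal EXPERIMENT_SET dialect written by convert_to_ena_xml().
     Deliberately a small subset of the SRA experiment schema: archive-side
     fields (accessions, study/platform blocks) are out of scope. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="qualified">
  <xs:element name="EXPERIMENT_SET">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="EXPERIMENT" minOccurs="0" maxOccurs="unbounded">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="SAMPLE_DESCRIPTOR" minOccurs="0">
                <xs:complexType>
                  <xs:attribute name="refname" type="xs:string" use="required"/>
                </xs:complexType>
              </xs:element>
              <xs:element name="EXPERIMENT_ATTRIBUTES" minOccurs="0">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="EXPERIMENT_ATTRIBUTE" minOccurs="0" maxOccurs="unbounded">
                      <xs:complexType>
                        <xs:sequence>
                          <xs:element name="TAG" type="xs:string"/>
                          <xs:element name="VALUE" type="xs:string"/>
                          <xs:element name="UNITS" type="xs:string" minOccurs="0"/>
                        </xs:sequence>
                      </xs:complexType>
                    </xs:element>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
            <xs:attribute name="alias" type="xs:string" use="required"/>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
    </xs:complexType>
  </xs:element>
</xs:schema>
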