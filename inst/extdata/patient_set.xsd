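<?xml version="1.0" encoding="UTF-8"?>
<!-- Schema for the minimal patient-set dialect read by parse_patient_set(). -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">
  <xs:element name="patient_set">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="patient" minOccurs="0" maxOccurs="unbounded">
          <xs:complexType>
            <xs:attribute name="id" type="xs:string" use="required"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="observation" minOccurs="0" maxOccurs="unbounded">
          <xs:complexType>
            <xs:attribute name="patient_id" type="xs:string" use="required"/>
            <xs:attribute name="concept_code" type="xs:string" use="required"/>
            <xs:attribute name="concept_label" type="xs:string" use="required"/>
            <xs:attribute name="value" type="xs:string"/>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
    </xs:complexType>
  </xs:element>
</xs:schema>
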