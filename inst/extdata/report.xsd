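<?xml version="1.0" encoding="UTF-8"?>
<!-- Schema of the nciprofiler XML interaction report, version 1.
     Interaction elements (one per detected contact) carry the measured
     geometry as attributes; attributes not applicable to a class are
     omitted, hence the permissive attribute model on interaction rows. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">

  <xs:complexType name="interactionType">
    <xs:attribute name="rec_residue" type="xs:string" use="required"/>
    <xs:attribute name="rec_chain" type="xs:string" use="required"/>
    <xs:attribute name="lig_residue" type="xs:string" use="required"/>
    <xs:attribute name="lig_chain" type="xs:string" use="required"/>
    <xs:attribute name="lig_serials" type="xs:string" use="required"/>
    <xs:attribute name="rec_serials" type="xs:string" use="required"/>
    <xs:attribute name="dist" type="xs:string" use="required"/>
    <xs:attribute name="receptor_is_nucleic" type="xs:string" use="required"/>
    <xs:anyAttribute processContents="skip"/>
  </xs:complexType>

  <xs:element name="interaction_profile">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="mode">
          <xs:complexType>
            <xs:anyAttribute processContents="skip"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="thresholds">
          <xs:complexType>
            <xs:anyAttribute processContents="skip"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="bindingsite" minOccurs="0" maxOccurs="unbounded">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="ligand">
                <xs:complexType>
                  <xs:attribute name="identifier" type="xs:string" use="required"/>
                  <xs:attribute name="kind" type="xs:string" use="required"/>
                  <xs:attribute name="composite" type="xs:string"/>
                  <xs:attribute name="residues" type="xs:string"/>
                </xs:complexType>
              </xs:element>
              <xs:element name="receptor">
                <xs:complexType>
                  <xs:anyAttribute processContents="skip"/>
                </xs:complexType>
              </xs:element>
              <xs:element name="interactions">
                <xs:complexType>
                  <xs:choice minOccurs="0" maxOccurs="unbounded">
                    <xs:element name="hydrophobic" type="interactionType"/>
                    <xs:element name="hbond" type="interactionType"/>
                    <xs:element name="waterbridge" type="interactionType"/>
                    <xs:element name="saltbridge" type="interactionType"/>
                    <xs:element name="pistacking" type="interactionType"/>
                    <xs:element name="pication" type="interactionType"/>
                    <xs:element name="halogen" type="interactionType"/>
                    <xs:element name="metal" type="interactionType"/>
                  </xs:choice>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
            <xs:attribute name="id" type="xs:string" use="required"/>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="engine" type="xs:string" use="required"/>
      <xs:attribute name="version" type="xs:string" use="required"/>
      <xs:anyAttribute processContents="skip"/>
    </xs:complexType>
  </xs:element>
</xs:schema>
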