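<?xml version="1.0" encoding="UTF-8"?>
<!--
  lrgkit record dialect, version 1.0.

  Strictness is asymmetric by design: the fixed_annotation section is a
  closed contract (unknown elements are schema violations), while the
  updatable_annotation section accepts arbitrary child elements after the
  mandatory source and modification_date, so that annotation sets written
  by newer tools survive validation and round trips.

  Constraints the XSD cannot express (interval orientation, agreement of
  the three exon coordinate systems, strand values, span geometry) are
  enforced by validate_xml()'s semantic stage and by validate_record().
-->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">

  <xs:simpleType name="dnaSequence">
    <xs:restriction base="xs:string">
      <xs:pattern value="[ACGTN]+"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="proteinSequence">
    <xs:restriction base="xs:string">
      <xs:pattern value="[ACDEFGHIKLMNPQRSTVWY]+"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="lrgId">
    <xs:restriction base="xs:string">
      <xs:pattern value="LRG_[1-9][0-9]*"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:element name="lrg">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="fixed_annotation">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="id" type="lrgId"/>
              <xs:element name="organism" minOccurs="0">
                <xs:complexType>
                  <xs:simpleContent>
                    <xs:extension base="xs:string">
                      <xs:attribute name="taxon_id" type="xs:positiveInteger"/>
                    </xs:extension>
                  </xs:simpleContent>
                </xs:complexType>
              </xs:element>
              <xs:element name="sequence" type="dnaSequence"/>
              <xs:element name="transcript" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="exon" maxOccurs="unbounded">
                      <xs:complexType>
                        <xs:attribute name="lrg_start" type="xs:positiveInteger" use="required"/>
                        <xs:attribute name="lrg_end" type="xs:positiveInteger" use="required"/>
                        <xs:attribute name="cdna_start" type="xs:positiveInteger" use="required"/>
                        <xs:attribute name="cdna_end" type="xs:positiveInteger" use="required"/>
                        <xs:attribute name="peptide_start" type="xs:positiveInteger"/>
                        <xs:attribute name="peptide_end" type="xs:positiveInteger"/>
                      </xs:complexType>
                    </xs:element>
                    <xs:element name="coding_region" minOccurs="0">
                      <xs:complexType>
                        <xs:attribute name="cds_start" type="xs:positiveInteger" use="required"/>
                        <xs:attribute name="cds_end" type="xs:positiveInteger" use="required"/>
                      </xs:complexType>
                    </xs:element>
                    <xs:element name="cdna_sequence" type="dnaSequence"/>
                    <xs:element name="translation" minOccurs="0">
                      <xs:complexType>
                        <xs:sequence>
                          <xs:element name="sequence" type="proteinSequence"/>
                        </xs:sequence>
                        <xs:attribute name="name" use="required">
                          <xs:simpleType>
                            <xs:restriction base="xs:string">
                              <xs:pattern value="p[1-9][0-9]*"/>
                            </xs:restriction>
                          </xs:simpleType>
                        </xs:attribute>
                      </xs:complexType>
                    </xs:element>
                  </xs:sequence>
                  <xs:attribute name="name" use="required">
                    <xs:simpleType>
                      <xs:restriction base="xs:string">
                        <xs:pattern value="t[1-9][0-9]*"/>
                      </xs:restriction>
                    </xs:simpleType>
                  </xs:attribute>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="updatable_annotation" minOccurs="0">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="annotation_set" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="source" type="xs:string"/>
                    <xs:element name="modification_date">
                      <xs:simpleType>
                        <xs:restriction base="xs:string">
                          <xs:pattern value="[0-9]{4}-[0-9]{2}-[0-9]{2}"/>
                        </xs:restriction>
                      </xs:simpleType>
                    </xs:element>
                    <xs:any namespace="##any" processContents="skip"
                            minOccurs="0" maxOccurs="unbounded"/>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="schema_dialect" type="xs:string" use="required"/>
    </xs:complexType>
  </xs:element>
</xs:schema>
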