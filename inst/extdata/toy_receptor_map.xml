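<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic toy receptor-signaling map (hand-written test fixture).
     Deliberately uses a different CellDesigner dialect than this package's
     writer: lower-case class tags, TRANSCRIPTION reaction type, PubMed
     URLs, attribute-order variations. Not derived from any real map. -->
<sbml xmlns="http://www.sbml.org/sbml/level2/version4"
      xmlns:celldesigner="http://www.sbml.org/2001/ns/celldesigner"
      level="2" version="4">
  <model id="toy" name="toy receptor map">
    <annotation>
      <celldesigner:extension>
        <celldesigner:listOfProteins>
          <celldesigner:protein id="pr1" name="RCP1" type="receptor"/>
          <celldesigner:protein id="pr2" name="ADP1" type="GENERIC"/>
          <celldesigner:protein id="pr3" name="TF1" type="GENERIC"/>
          <celldesigner:protein id="pr4" name="TRP1" type="TRUNCATED"/>
        </celldesigner:listOfProteins>
      </celldesigner:extension>
    </annotation>
    <listOfCompartments>
      <compartment id="membrane"/>
      <compartment id="cytoplasm"/>
      <compartment id="nucleus"/>
    </listOfCompartments>
    <listOfSpecies>
      <species compartment="membrane" id="sp1" name="RCP1">
        <annotation>
          <celldesigner:extension>
            <celldesigner:speciesIdentity>
              <celldesigner:class>protein</celldesigner:class>
              <celldesigner:proteinReference>pr1</celldesigner:proteinReference>
            </celldesigner:speciesIdentity>
          </celldesigner:extension>
        </annotation>
        <notes><body xmlns="http://www.w3.org/1999/xhtml">
          receptor; http://www.ncbi.nlm.nih.gov/gene/7099
          http://www.ncbi.nlm.nih.gov/pubmed/11607032
        </body></notes>
      </species>
      <species id="sp2" name="ADP1" compartment="cytoplasm">
        <annotation>
          <celldesigner:extension>
            <celldesigner:speciesIdentity>
              <celldesigner:class>PROTEIN</celldesigner:class>
              <celldesigner:proteinReference>pr2</celldesigner:proteinReference>
            </celldesigner:speciesIdentity>
            <celldesigner:activity>active</celldesigner:activity>
            <celldesigner:listOfModifications>
              <celldesigner:modification state="phosphorylated"/>
            </celldesigner:listOfModifications>
          </celldesigner:extension>
        </annotation>
        <notes><body xmlns="http://www.w3.org/1999/xhtml">PMID: 9013863, PMID 9697844; GeneID: 4615</body></notes>
      </species>
      <species id="sp3" name="TF1" compartment="cytoplasm">
        <annotation>
          <celldesigner:extension>
            <celldesigner:speciesIdentity>
              <celldesigner:class>PROTEIN</celldesigner:class>
              <celldesigner:proteinReference>pr3</celldesigner:proteinReference>
            </celldesigner:speciesIdentity>
          </celldesigner:extension>
        </annotation>
      </species>
      <species id="sp4" name="TRP1" compartment="cytoplasm">
        <annotation>
          <celldesigner:extension>
            <celldesigner:speciesIdentity>
              <celldesigner:class>PROTEIN</celldesigner:class>
              <celldesigner:proteinReference>pr4</celldesigner:proteinReference>
            </celldesigner:speciesIdentity>
          </celldesigner:extension>
        </annotation>
      </species>
      <species id="sp5" name="ifnx mRNA" compartment="nucleus">
        <annotation>
          <celldesigner:extension>
            <celldesigner:speciesIdentity>
              <celldesigner:class>rna</celldesigner:class>
            </celldesigner:speciesIdentity>
          </celldesigner:extension>
        </annotation>
      </species>
      <species id="sp6" name="RCP1:ADP1" compartment="membrane">
        <annotation>
          <celldesigner:extension>
            <celldesigner:speciesIdentity>
              <celldesigner:class>COMPLEX</celldesigner:class>
            </celldesigner:speciesIdentity>
          </celldesigner:extension>
        </annotation>
      </species>
      <species id="sp7" name="mystery factor" compartment="cytoplasm"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="r1" reversible="false">
        <annotation>
          <celldesigner:extension>
            <celldesigner:reactionType>HETERODIMER_ASSOCIATION</celldesigner:reactionType>
          </celldesigner:extension>
        </annotation>
        <notes><body xmlns="http://www.w3.org/1999/xhtml">PMID: 11607032</body></notes>
        <listOfReactants>
          <speciesReference species="sp1"/>
          <speciesReference species="sp2"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="sp6"/>
        </listOfProducts>
      </reaction>
      <reaction id="r2" reversible="false">
        <annotation>
          <celldesigner:extension>
            <celldesigner:reactionType>STATE_TRANSITION</celldesigner:reactionType>
            <celldesigner:listOfModification>
              <celldesigner:modification type="CATALYSIS" modifiers="sp6"/>
            </celldesigner:listOfModification>
          </celldesigner:extension>
        </annotation>
        <listOfReactants>
          <speciesReference species="sp3"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="sp4"/>
        </listOfProducts>
        <listOfModifiers>
          <modifierSpeciesReference species="sp6"/>
        </listOfModifiers>
      </reaction>
      <reaction id="r3" reversible="false">
        <annotation>
          <celldesigner:extension>
            <celldesigner:reactionType>TRANSCRIPTION</celldesigner:reactionType>
          </celldesigner:extension>
        </annotation>
        <listOfReactants>
          <speciesReference species="sp4"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="sp5"/>
        </listOfProducts>
      </reaction>
      <reaction id="r4" reversible="false">
        <notes><body xmlns="http://www.w3.org/1999/xhtml">mechanism carries a question mark in the diagram</body></notes>
        <listOfReactants>
          <speciesReference species="sp7"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="sp3"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
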