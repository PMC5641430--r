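<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="toy_l2" name="small Level 2 test model">
    <listOfCompartments>
      <compartment id="cytosol"/>
      <compartment id="ext"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="X" name="external X" compartment="ext" boundaryCondition="true"/>
      <species id="A" name="compound A" compartment="cytosol"/>
      <species id="B" name="compound B" compartment="cytosol"/>
      <species id="C" name="compound C" compartment="cytosol"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R_in" reversible="false">
        <listOfProducts>
          <speciesReference species="A"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci> FLUX_VALUE </ci></math>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="10"/>
            <parameter id="FLUX_VALUE" value="0"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="R1" reversible="true">
        <listOfReactants>
          <speciesReference species="A"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci> FLUX_VALUE </ci></math>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="-5"/>
            <parameter id="UPPER_BOUND" value="8"/>
            <parameter id="FLUX_VALUE" value="0"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="R_x" reversible="false">
        <listOfReactants>
          <speciesReference species="X"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="C" stoichiometry="2"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci> FLUX_VALUE </ci></math>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="4"/>
            <parameter id="FLUX_VALUE" value="0"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="R_bio" reversible="false">
        <listOfReactants>
          <speciesReference species="B"/>
          <speciesReference species="C"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
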