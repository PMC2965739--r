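<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy" fbc:strict="true">
    <listOfCompartments>
      <compartment id="e" constant="true"/>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A_e" compartment="e" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="A_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="B_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="C_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="D_e" compartment="e" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_ex" value="-10" constant="true"/>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_inf" value="1000" constant="true"/>
    </listOfParameters>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="gp_G1" fbc:label="G1"/>
      <fbc:geneProduct fbc:id="gp_G2" fbc:label="G2"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="EX_A" reversible="true" fast="false" fbc:lowerFluxBound="lb_ex" fbc:upperFluxBound="ub_inf">
        <listOfReactants>
          <speciesReference species="A_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="T_A" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_inf">
        <listOfReactants>
          <speciesReference species="A_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="A_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_AB" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_inf">
        <listOfReactants>
          <speciesReference species="A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_BC" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_inf">
        <listOfReactants>
          <speciesReference species="B_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="C_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="gp_G1"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_AD" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_inf">
        <listOfReactants>
          <speciesReference species="A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="D_e" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="gp_G2"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="EX_D" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_inf">
        <listOfReactants>
          <speciesReference species="D_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="Biomass" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_inf">
        <listOfReactants>
          <speciesReference species="C_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="Biomass" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>
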