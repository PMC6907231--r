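# Element-path -> record-field mapping for ELN-export XML. The default
# covers the synthetic fixture dialect; adapt for other ELN exports.
payload_element: CDXML
table_row_xpath: ".//reactionTable/row"
fields:
  role: role
  identifier: identifier
  amounts: amount
  conditions: conditions
  observations: observations
role_map:
  startingMaterial: reactant
  reactant: reactant
  reagent: reagent
  catalyst: reagent
  solvent: solvent
  product: product
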