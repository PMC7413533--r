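# Region configuration for the ZitR homodimer (147 residues per monomer).
# Secondary-structure residue ranges are NOT bundled with the package: they
# must be taken from the structure annotation of the deposited entries.
# The ranges below are illustrative placeholders showing the schema; the
# probe residue (A71, the recognition-helix C-alpha pair) and the chain
# layout are the package defaults.
chains: [A, B]
elements:
  alpha2: [38, 50]      # placeholder range: replace from the annotation
  beta2: [90, 96]       # placeholder range: replace from the annotation
dna_binding_domain: [38, 96]   # alpha2 start -> beta2 end
probe_residue: 71
temperature: 300
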