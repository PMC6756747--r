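# Mass deltas (Da) of the post-translational modifications considered.
# "amidation" is the amide-vs-free-acid delta; the loss of the
# C-terminal glycine of a glycine-extended peptide is handled at the
# sequence level (the G residue mass is subtracted when the residue is
# removed), so the full glycine-loss amidation delta is
# amidation - mass(G) = -58.005476 Da.
name	delta
amidation	-0.984016
pyroglu_Q	-17.026549
pyroglu_E	-18.010565
oxidation_M	15.994915
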