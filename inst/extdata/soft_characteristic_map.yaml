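# Mapping from SOFT !Sample_characteristics keys (lowercased) to biomaterial
# fields. Edit or extend freely; unmapped keys fall through to the notes.
organism: organism
cell type: cell_type
cell_type: cell_type
tissue: tissue
development stage: development_stage
developmental stage: development_stage
disease state: disease_state
disease: disease_state
diagnosis: disease_state
treatment: treatment
age: age
sex: sex
gender: sex
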