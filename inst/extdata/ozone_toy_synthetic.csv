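"Chemical","Chemical.ID","Gene","Gene.ID","Phenotype","Phenotype.ID","Disease","Disease.ID"
"Ozone","D010126","PTGFR","5737","inflammatory response","GO:0006954","Airway Obstruction","D000402"
"Ozone","D010126","PTGFR","5737","response to lipopolysaccharide","GO:0032496","Airway Obstruction","D000402"
"Ozone","D010126","TFPI","7035","response to lipopolysaccharide","GO:0032496","Airway Obstruction","D000402"
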