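format-version: 1.2
ontology: synthetic-mini

[Term]
id: GO:0008150
name: biological_process

[Term]
id: GO:0050896
name: response to stimulus
is_a: GO:0008150 ! biological_process

[Term]
id: GO:0009593
name: detection of chemical stimulus
is_a: GO:0050896 ! response to stimulus

[Term]
id: GO:0006950
name: response to stress
is_a: GO:0050896 ! response to stimulus

[Term]
id: GO:0033554
name: cellular response to stress
is_a: GO:0006950 ! response to stress

[Term]
id: GO:0000001
name: obsolete example term
is_a: GO:0008150
is_obsolete: true
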