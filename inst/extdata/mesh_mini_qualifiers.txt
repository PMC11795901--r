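# miniature synthetic MeSH qualifier list for tests and examples
diagnosis
therapy
drug therapy
surgery
epidemiology
etiology
prevention & control
psychology
mortality
genetics
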