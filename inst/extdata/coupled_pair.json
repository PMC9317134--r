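{"metabolites":"D","reactions":[{"id":"R4","stoichiometry":{"D":1},"lb":0,"ub":1e+30},{"id":"R10","stoichiometry":{"D":-1},"lb":0,"ub":1e+30}]}
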