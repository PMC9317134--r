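{"metabolites":["A","B","C","D","E","F"],"reactions":[{"id":"R1","stoichiometry":{"A":1},"lb":0,"ub":1e+30},{"id":"R2","stoichiometry":{"B":1},"lb":-1e+30,"ub":1e+30},{"id":"R3","stoichiometry":{"E":-1},"lb":0,"ub":1e+30},{"id":"R4","stoichiometry":{"F":-1},"lb":0,"ub":1e+30},{"id":"R5","stoichiometry":{"A":-1,"C":1},"lb":0,"ub":1e+30},{"id":"R6","stoichiometry":{"A":-1,"E":1},"lb":0,"ub":1e+30},{"id":"R7","stoichiometry":{"A":-1,"D":1},"lb":0,"ub":1e+30},{"id":"R8","stoichiometry":{"C":-1,"E":1},"lb":-1e+30,"ub":1e+30},{"id":"R9","stoichiometry":{"B":-1,"E":1},"lb":0,"ub":1e+30},{"id":"R10","stoichiometry":{"D":-1,"F":1},"lb":0,"ub":1e+30}]}
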