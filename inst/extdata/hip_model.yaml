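# Five-state hip osteoarthritis transition structure.
# A: no radiographic hip OA (rHOA), no symptoms
# B: asymptomatic rHOA          C: hip symptoms only
# D: symptomatic hip OA         E: death (absorbing)
# The diagonal moves A->D and C->B are excluded as instantaneous
# transitions; observed A/D and C/B panel pairs occur via two jumps.
states: [A, B, C, D, E]
labels:
  A: No rHOA/symptoms
  B: Asymptomatic rHOA
  C: Symptoms only
  D: Symptomatic HOA
  E: Death
absorbing: [E]
transitions:
  - A -> B
  - A -> C
  - C -> A
  - C -> D
  - B -> D
  - D -> B
  - A -> E
  - B -> E
  - C -> E
  - D -> E
covariates:
  names: [age0_c, male, black, educ_lt12, enrich, byear_c,
          obesity, dm, cvd, hip_injury]
  kind: [static, static, static, static, static, static,
         time-dependent, time-dependent, time-dependent, time-dependent]
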