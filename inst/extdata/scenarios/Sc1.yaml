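schema_version: 1
id: Sc1
populations:
- SAG
- NAG
- NC
initial_sizes:
  SAG: N_SAG
  NAG: N_NAG
  NC: N_NC
mutation_param: mu
events:
- time: t_exp
  kind: resize
  pop: SAG
  pop2: .na.character
  param: N1
- time: t_exp
  kind: resize
  pop: NAG
  pop2: .na.character
  param: N2
- time: t_exp
  kind: resize
  pop: NC
  pop2: .na.character
  param: N3
- time: t_2
  kind: merge
  pop: NAG
  pop2: SAG
  param: .na.character
- time: t_2
  kind: resize
  pop: SAG
  pop2: .na.character
  param: N4
- time: t_3
  kind: merge
  pop: SAG
  pop2: NC
  param: .na.character
- time: t_3
  kind: resize
  pop: NC
  pop2: .na.character
  param: N_anc
priors:
- param: N_anc
  low: 1000.0
  high: 60000.0
  log_scale: no
- param: N_SAG
  low: 100000.0
  high: 3600000.0
  log_scale: no
- param: N_NAG
  low: 150000.0
  high: 800000.0
  log_scale: no
- param: N_NC
  low: 40000.0
  high: 150000.0
  log_scale: no
- param: N1
  low: 100.0
  high: 200000.0
  log_scale: no
- param: N2
  low: 100.0
  high: 200000.0
  log_scale: no
- param: N3
  low: 100.0
  high: 200000.0
  log_scale: no
- param: N4
  low: 100.0
  high: 200000.0
  log_scale: no
- param: t_exp
  low: 60000.0
  high: 450000.0
  log_scale: no
- param: t_2
  low: 50000.0
  high: 350000.0
  log_scale: no
- param: t_3
  low: 100000.0
  high: 1000000.0
  log_scale: no
- param: mu
  low: 1.0e-11
  high: 1.0e-07
  log_scale: no
constraints:
- lhs: t_exp
  op: <=
  rhs: t_2
- lhs: t_2
  op: <
  rhs: t_3
- lhs: N_anc
  op: <
  rhs: N_NC
- lhs: N_NC
  op: <=
  rhs: N_NAG
- lhs: N_NAG
  op: <=
  rhs: N_SAG
- lhs: N1
  op: '>'
  rhs: N_anc
- lhs: N2
  op: '>'
  rhs: N_anc
- lhs: N3
  op: '>'
  rhs: N_anc
- lhs: N4
  op: '>'
  rhs: N_anc
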