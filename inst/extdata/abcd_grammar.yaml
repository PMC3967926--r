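start: Start
exit: Exit
arcs:
- from: Start
  to: g1_1
  symbol: A
  prob: 0.25
- from: g1_1
  to: g1_2
  symbol: A
  prob: 1.0
- from: g1_2
  to: g1_3
  symbol: B
  prob: 1.0
- from: g1_3
  to: Exit
  symbol: C
  prob: 1.0
- from: Start
  to: g2_1
  symbol: A
  prob: 0.25
- from: g2_1
  to: g2_2
  symbol: B
  prob: 1.0
- from: g2_2
  to: g2_3
  symbol: A
  prob: 1.0
- from: g2_3
  to: Exit
  symbol: D
  prob: 1.0
- from: Start
  to: g3_1
  symbol: B
  prob: 0.25
- from: g3_1
  to: g3_2
  symbol: B
  prob: 1.0
- from: g3_2
  to: g3_3
  symbol: A
  prob: 1.0
- from: g3_3
  to: Exit
  symbol: C
  prob: 1.0
- from: Start
  to: g4_1
  symbol: B
  prob: 0.25
- from: g4_1
  to: g4_2
  symbol: A
  prob: 1.0
- from: g4_2
  to: g4_3
  symbol: B
  prob: 1.0
- from: g4_3
  to: Exit
  symbol: D
  prob: 1.0
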