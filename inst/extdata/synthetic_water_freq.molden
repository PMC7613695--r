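[Molden Format]
[FREQ]
1595.0
3657.0
3756.0
[FR-COORD]
O  0.000000  0.000000  0.222000
H  0.000000  1.430000 -0.886000
H  0.000000 -1.430000 -0.886000
[FR-NORM-COORD]
vibration 1
   0.00000000   0.00000000   0.00000000
   0.00000000   0.70429521   0.00000000
   0.00000000  -0.70429521   0.00000000
vibration 2
   0.00000000   0.00000000   0.00000000
   0.00000000   0.70429521   0.00000000
   0.00000000   0.70429521   0.00000000
vibration 3
   0.00000000   0.00000000   0.25000781
   0.00000000   0.00000000   0.00000000
   0.00000000   0.00000000   0.00000000
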