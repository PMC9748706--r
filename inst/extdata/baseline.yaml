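'r1': 10
'c1': 2
'c2': 3
'c3': 16
'c4': 20
'e1': 6
'e2': 8
'e3': 5
'L': 2
'h1': 2
'h2': 4
'h3': 2
'h4': 3
'w1': 10
'M': 4
'N': 4
't1': 12
't2': 12
'F1': 4
'F2': 3
'F3': 3
'G': 3
'alpha': 0.90000000000000002
'beta': 0.90000000000000002
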