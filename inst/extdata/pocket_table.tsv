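P1	82,85,86,89
P2	77,78,81,82
P3	78
P4	11,13,26,28,70,71,74,78
P5	11,13,28,70,71,74
P6	11,13,28,30,61,71
P7	11,28,30,47,61,67,70,71
P8	60,61
P9	9,30,37,57,60,61
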