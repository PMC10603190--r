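library	arm	class	rate
tumor1	bs	C	99.35
tumor2	bs	C	99.35
tumor3	bs	C	99.37
tumor4	bs	C	99.28
normal1	bs	C	99.31
normal2	bs	C	99.29
normal3	bs	C	99.38
normal4	bs	C	99.32
tumor1	bs	5fC	60.22
tumor2	bs	5fC	58.48
tumor3	bs	5fC	59.95
tumor4	bs	5fC	58.48
normal1	bs	5fC	59.50
normal2	bs	5fC	58.79
normal3	bs	5fC	60.75
normal4	bs	5fC	59.55
tumor1	bs	5mC	3.95
tumor2	bs	5mC	3.74
tumor3	bs	5mC	3.89
tumor4	bs	5mC	3.95
normal1	bs	5mC	3.79
normal2	bs	5mC	3.76
normal3	bs	5mC	3.76
normal4	bs	5mC	3.81
tumor1	bs	5hmC	4.76
tumor2	bs	5hmC	4.90
tumor3	bs	5hmC	4.80
tumor4	bs	5hmC	5.00
normal1	bs	5hmC	4.62
normal2	bs	5hmC	4.72
normal3	bs	5hmC	4.99
normal4	bs	5hmC	5.32
tumor1	ox	C	99.37
tumor2	ox	C	99.42
tumor3	ox	C	99.39
tumor4	ox	C	99.45
normal1	ox	C	99.41
normal2	ox	C	99.37
normal3	ox	C	99.46
normal4	ox	C	99.39
tumor1	ox	5fC	92.22
tumor2	ox	5fC	93.12
tumor3	ox	5fC	91.81
tumor4	ox	5fC	91.25
normal1	ox	5fC	92.55
normal2	ox	5fC	92.39
normal3	ox	5fC	92.41
normal4	ox	5fC	92.42
tumor1	ox	5mC	3.10
tumor2	ox	5mC	3.28
tumor3	ox	5mC	3.12
tumor4	ox	5mC	3.56
normal1	ox	5mC	3.19
normal2	ox	5mC	3.05
normal3	ox	5mC	3.13
normal4	ox	5mC	3.26
tumor1	ox	5hmC	96.52
tumor2	ox	5hmC	96.39
tumor3	ox	5hmC	96.57
tumor4	ox	5hmC	96.56
normal1	ox	5hmC	96.78
normal2	ox	5hmC	96.43
normal3	ox	5hmC	96.56
normal4	ox	5hmC	96.31
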