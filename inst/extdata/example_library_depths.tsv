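library	arm	depth
tumor1	bs	27.54
tumor2	bs	27.48
tumor3	bs	27.43
tumor4	bs	30.14
normal1	bs	27.34
normal2	bs	27.33
normal3	bs	33.81
normal4	bs	28.50
tumor1	ox	30.57
tumor2	ox	29.47
tumor3	ox	30.86
tumor4	ox	28.68
normal1	ox	28.17
normal2	ox	27.39
normal3	ox	28.22
normal4	ox	28.35
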