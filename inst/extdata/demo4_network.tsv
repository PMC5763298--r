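v2	v1	-
v3	v2	-
v4	v2	-
v4	v3	+
v1	v4	-
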