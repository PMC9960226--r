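# Synthetic non-essential reference set (fixture only); see the note in
# synthetic_essential_genes.txt.
SYNNON001
SYNNON002
SYNNON003
SYNNON004
SYNNON005
SYNNON006
SYNNON007
SYNNON008
SYNNON009
SYNNON010
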