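# Synthetic essential-gene reference set (fixture only).
# These are NOT a curated core-essential list; they are placeholder symbols
# matching the simulator's naming so that file-based benchmarking workflows
# can be exercised end to end. Supply your own curated lists for real data.
SYNESS001
SYNESS002
SYNESS003
SYNESS004
SYNESS005
SYNESS006
SYNESS007
SYNESS008
SYNESS009
SYNESS010
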