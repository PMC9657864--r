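# Default activity-code mapping: codes 1-5 are the five fall activities,
# 6-11 the six activities of daily living, 12 the synthetic recovered
# near-fall. Copy and edit to relabel a custom dataset.
'1': fall
'2': fall
'3': fall
'4': fall
'5': fall
'6': not_fall
'7': not_fall
'8': not_fall
'9': not_fall
'10': not_fall
'11': not_fall
'12': not_fall
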