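glucose	D09.400.410
l-tyrosine	D12.125.072.901
melatonin	D03.633.100.473
serine	D12.125.072.850
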