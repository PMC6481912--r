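dementia	C10.228.140.380
alzheimer disease	C10.228.140.380.100
huntington disease	C10.228.140.380.278
frontotemporal dementia	C10.228.140.380.266
lewy body dementia	C10.228.140.380.422
parkinson disease	C10.228.140.079.862.500
supranuclear palsy, progressive	C10.228.140.079.862.800
multiple system atrophy	C10.228.140.079.590
myoclonus	C10.228.140.079.611
amyloidosis	C18.452.845.500
tumor	C04.588
amyloid plaque	C18.452.845.800
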