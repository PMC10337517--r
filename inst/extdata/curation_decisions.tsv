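mention	cui	status
typediabetes	C0011854	mapped
highcholesterol	C0020443	mapped
rectal ca	C0007113	mapped
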