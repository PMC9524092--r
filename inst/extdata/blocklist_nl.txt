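# class label mentions
migraine
clusterhoofdpijn
cluster
aanvalshoofdpijn
# medication and treatment references that hint at the diagnosis
medicatie
ibuprofen
paracetamol
sumatriptan
rizatriptan
triptaan
triptanen
verapamil
lithium
zuurstof
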