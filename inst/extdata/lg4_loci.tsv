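lg4_id	chrom	start	end
Chr5_LG4	Chr5	551935	556936
Chr12_LG4	Chr12	132685134	132690031
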