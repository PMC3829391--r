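{"gene_id":"1","gene_symbol":"FAM129B","aliases":["MEG-3","MINERVA"],"description":"Niban-like protein 1, associated with melanoma invasion","summary":"Phosphorylated downstream of MEK/ERK signalling."}
{"gene_id":"2","gene_symbol":"KEAP1","aliases":[],"description":"Kelch-like ECH-associated protein 1","summary":"Substrate adaptor for the CUL3 ubiquitin ligase."}
{"gene_id":"3","gene_symbol":"AXIN2","aliases":["conductin"],"description":"Axis inhibition protein 2","summary":"Negative feedback target of Wnt/beta-catenin signalling."}
{"gene_id":"4","gene_symbol":"DECOYA","aliases":[],"description":"Putative driver of melanomagenesis","summary":"Substring-only decoy."}
{"gene_id":"5","gene_symbol":"MLANA","aliases":["MART-1"],"description":"Melanoma antigen recognized by T cells","summary":"Melanocyte differentiation antigen, melanoma marker."}
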