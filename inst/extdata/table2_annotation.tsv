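sample_id	role	site	month	batch
Sample_1	wastewater	A	May	
Sample_2	wastewater	A	June	
Sample_3	wastewater	A	July	
Sample_4	wastewater	A	August	
Sample_5	wastewater	A	September	
Sample_6	wastewater	A	November	
Sample_7	wastewater	A	January	
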