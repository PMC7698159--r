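name	gene_id
VviAP1	VIT_201s0011g00100
VviAIL2	VIT_209s0002g01370
VviSOC1a	VIT_215s0048g01250
VviDRM1	VIT_210s0003g00090
VviSVP1	VIT_200s0313g00070
VviFLC1	VIT_201s0010g03890
VviFLC2	VIT_214s0068g01800
VviTM8a	VIT_217s0000g01230
VviMYBC2-L1	VIT_201s0011g04760
VviMYB4A	VIT_203s0038g02310
VviMYBPAR	VIT_211s0016g01300
VviMYB15	VIT_205s0049g01020
VviMYB14	VIT_205s0049g01020
VviMYB30A	VIT_217s0000g06190
VviMYBPA1	VIT_215s0046g00170
VviMYB174	VIT_218s0001g09850
VviMYBA1	VIT_202s0033g00410
VviWRKY20	VIT_207s0005g02570
VviWRKY31	VIT_210s0003g02810
VvWRKY23	VIT_207s0031g01840
VviWRKY41	VIT_213s0067g03140
VviWRKY25	VIT_208s0058g01390
VviWRKY16	VIT_206s0004g07500
VviWRKY45	VIT_214s0108g01280
VviWRKY33	VIT_211s0037g00150
VviUBQ10	VIT_219s0177g00040
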