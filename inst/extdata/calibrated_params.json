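{"k_homeostasis":0.006889,"k_EH":1.885673,"k_HK":0.016022,"k_HM":0.035359,"k_HE":0.003318,"k_ME":0.049222}
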