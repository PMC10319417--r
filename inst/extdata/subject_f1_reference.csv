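subject,class,pairing,f1
H1,Class1,no-LMI/rest,63.9
H2,Class1,no-LMI/rest,66.8
H3,Class1,no-LMI/rest,78.7
H4,Class1,no-LMI/rest,65
H5,Class1,no-LMI/rest,75.0
H6,Class1,no-LMI/rest,80.5
H7,Class1,no-LMI/rest,83.0
H8,Class1,no-LMI/rest,87.7
H9,Class1,no-LMI/rest,70.8
H10,Class1,no-LMI/rest,86.7
H11,Class1,no-LMI/rest,65.1
H12,Class1,no-LMI/rest,80.2
H13,Class1,no-LMI/rest,66.9
H14,Class1,no-LMI/rest,74.1
H15,Class1,no-LMI/rest,64.9
H16,Class1,no-LMI/rest,79.5
H1,Class2,KI-LMI/rest,76
H2,Class2,KI-LMI/rest,70.1
H3,Class2,KI-LMI/rest,74.9
H4,Class2,KI-LMI/rest,76.1
H5,Class2,KI-LMI/rest,77.3
H6,Class2,KI-LMI/rest,87.9
H7,Class2,KI-LMI/rest,84.2
H8,Class2,KI-LMI/rest,93.8
H9,Class2,KI-LMI/rest,82.1
H10,Class2,KI-LMI/rest,92
H11,Class2,KI-LMI/rest,80
H12,Class2,KI-LMI/rest,94.8
H13,Class2,KI-LMI/rest,77.3
H14,Class2,KI-LMI/rest,81.7
H15,Class2,KI-LMI/rest,78.5
H16,Class2,KI-LMI/rest,83.7
H1,Class3,KI-LMI/V-rest,81
H2,Class3,KI-LMI/V-rest,65.5
H3,Class3,KI-LMI/V-rest,58.3
H4,Class3,KI-LMI/V-rest,71.1
H5,Class3,KI-LMI/V-rest,69.1
H6,Class3,KI-LMI/V-rest,88.2
H7,Class3,KI-LMI/V-rest,72.3
H8,Class3,KI-LMI/V-rest,92.3
H9,Class3,KI-LMI/V-rest,83.9
H10,Class3,KI-LMI/V-rest,86.1
H11,Class3,KI-LMI/V-rest,69.3
H12,Class3,KI-LMI/V-rest,81.4
H13,Class3,KI-LMI/V-rest,72.9
H14,Class3,KI-LMI/V-rest,79.1
H15,Class3,KI-LMI/V-rest,68.9
H16,Class3,KI-LMI/V-rest,83.5
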