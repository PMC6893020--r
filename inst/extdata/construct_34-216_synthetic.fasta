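>construct_34-216_synthetic synthetic stand-in for the Bla g 1.0101 residues 34-216 construct (not the GenBank AF072219 sequence); positions 23-31 = LAVIPWAIV
LQPVIHTGNIHFVRDVRDFPADLAVIPWAIVANSLMEQLKRFHIIRRAVHQNGIRAFVEC
QVNVVTISTIGARKWHTAKFNREVINVAEERKGPLCARNPSIDCETEGYGRVEAEMVTPD
YQAERTPVDRPGTTTLFNIEYVGGAGMDKGLRTRADGGIVDSTTLGQFLPAKCIACDNIQ
IVT
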