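CRDAMVZIKSXKFV	simulated-genus-records
HCJMNOSIAGSZBM	simulated-genus-records
KZNIFHPLKGYRTM	simulated-genus-records
LUKBXSAWLPMMSZ	simulated-genus-records
PLVPPLCLBIEYEA	simulated-genus-records
QCDYQQDYXPDABM	simulated-genus-records
VFLDPWHFBUODDF	simulated-genus-records
WBYWAXJHAXSJNI	simulated-genus-records
YGSDEFSMJLZEOE	simulated-genus-records
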