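>serf_synthetic synthetic 68-residue SERF-like protein; composition matched to published description (net charge +12, one proline, nine arginines)
MARSNQKELAKGKNSKKDQQKVRGKASRPHKGVSSEKAREDMAKREKDARKEGNIEKDAR
QKEKARRD
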