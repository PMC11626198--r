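2026-09-29T14:45:58 command: frobnicate seed: 1 package: idrbind 0.1.0
2026-09-29T14:45:58 exit: 2
2026-09-29T14:52:01 command: frobnicate seed: 1 package: idrbind 0.1.0
2026-09-29T14:52:01 exit: 2
2026-09-29T15:33:04 command: frobnicate seed: 1 package: idrbind 0.1.0
2026-09-29T15:33:04 exit: 2
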