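{
  "subcommand": "score",
  "flags": {
    "N": "10",
    "G": "4",
    "s": "3",
    "f": "2"
  },
  "seed": 1,
  "package": "xtalknet",
  "version": "0.1.0",
  "r_version": "4.3.3"
}
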