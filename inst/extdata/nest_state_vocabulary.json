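{
  "structure": ["scrape", "platform", "cup", "simple dome", "dome with tunnel", "primary cavity", "secondary cavity"],
  "site": ["ground", "tree", "non-tree vegetation", "cliff/bank", "underground", "water bodies", "termite/ant nests"],
  "attachment": ["basal", "lateral", "horizontally forked", "pensile"]
}
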