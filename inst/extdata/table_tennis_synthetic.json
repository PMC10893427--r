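{
  "classes": ["fh_drive", "bh_drive", "fh_loop", "bh_loop", "fh_block", "bh_block", "fh_push", "bh_push"],
  "sequences": [
    ["fh_drive"],
    ["fh_block"],
    ["bh_drive"],
    ["bh_loop"],
    ["bh_push"],
    ["fh_push"],
    ["bh_block"],
    ["fh_loop"],
    ["fh_drive", "fh_drive"],
    ["fh_loop", "bh_loop"],
    ["fh_block", "fh_push"],
    ["fh_block", "fh_block"],
    ["bh_loop", "bh_drive"],
    ["bh_loop", "bh_push"],
    ["fh_loop", "bh_drive", "fh_drive"],
    ["bh_drive", "bh_push", "bh_block"],
    ["fh_loop", "fh_push", "bh_block"],
    ["bh_drive", "bh_push", "bh_loop"],
    ["bh_loop", "bh_block", "bh_drive"],
    ["fh_block", "bh_loop", "fh_block"],
    ["bh_loop", "bh_drive", "bh_push", "bh_drive"],
    ["fh_loop", "bh_push", "fh_push", "fh_drive"],
    ["fh_block", "bh_drive", "bh_drive", "bh_block"],
    ["bh_block", "bh_drive", "bh_loop", "fh_loop"],
    ["bh_block", "fh_block", "bh_drive", "fh_push"],
    ["bh_block", "bh_drive", "bh_drive", "bh_push"],
    ["fh_block", "fh_drive", "fh_drive", "fh_push", "bh_loop"],
    ["fh_block", "bh_drive", "fh_drive", "fh_block", "bh_loop"],
    ["bh_loop", "fh_drive", "fh_loop", "fh_loop", "fh_block"],
    ["bh_push", "fh_block", "bh_loop", "bh_push", "bh_block"],
    ["fh_block", "bh_loop", "bh_block", "bh_drive", "bh_drive"],
    ["bh_push", "fh_drive", "bh_drive", "fh_block", "bh_block"],
    ["bh_push", "fh_push", "bh_push", "fh_block", "bh_loop", "fh_drive"],
    ["bh_loop", "fh_push", "bh_drive", "bh_drive", "fh_loop", "fh_block"],
    ["fh_block", "bh_block", "fh_loop", "bh_push", "bh_push", "bh_block"],
    ["bh_loop", "fh_block", "fh_drive", "bh_loop", "fh_drive", "fh_drive"],
    ["fh_block", "bh_block", "fh_loop", "fh_drive", "bh_drive", "bh_push"],
    ["bh_push", "fh_block", "fh_push", "bh_block", "fh_drive", "fh_block"],
    ["bh_block", "fh_block", "fh_drive", "fh_push", "bh_push", "bh_drive", "fh_loop"],
    ["bh_drive", "bh_drive", "bh_push", "fh_drive", "fh_loop", "fh_drive", "fh_block"],
    ["fh_drive", "fh_loop", "fh_push", "bh_push", "fh_drive", "bh_block", "bh_block"],
    ["fh_push", "bh_block", "bh_push", "fh_push", "fh_loop", "bh_block", "fh_block"],
    ["bh_push", "fh_drive", "bh_push", "bh_block", "fh_drive", "bh_drive", "fh_push"],
    ["bh_drive", "bh_block", "bh_push", "bh_block", "bh_block", "bh_block", "fh_push", "bh_block"],
    ["bh_loop", "bh_loop", "fh_push", "bh_drive", "bh_drive", "fh_push", "bh_loop", "bh_block"],
    ["bh_loop", "bh_push", "bh_drive", "fh_drive", "fh_drive", "bh_drive", "bh_push", "bh_push"],
    ["bh_drive", "fh_drive", "bh_loop", "fh_loop", "fh_block", "bh_block", "bh_block", "bh_drive"],
    ["bh_loop", "bh_drive", "fh_push", "bh_push", "fh_loop", "bh_drive", "fh_drive", "bh_loop"],
    ["bh_block", "fh_block", "bh_drive", "fh_drive", "fh_drive", "fh_block", "fh_loop", "bh_block", "bh_block"],
    ["bh_loop", "bh_drive", "fh_drive", "fh_block", "fh_loop", "bh_block", "bh_drive", "fh_push", "fh_push"],
    ["fh_block", "fh_loop", "bh_loop", "bh_drive", "bh_push", "fh_drive", "fh_loop", "fh_loop", "bh_block"],
    ["bh_loop", "bh_loop", "bh_loop", "fh_loop", "fh_drive", "fh_drive", "fh_drive", "bh_block", "fh_block"],
    ["fh_push", "bh_block", "bh_loop", "fh_push", "fh_drive", "fh_block", "bh_loop", "fh_drive", "fh_drive", "fh_drive"],
    ["bh_loop", "bh_drive", "fh_push", "bh_push", "fh_push", "bh_push", "fh_loop", "fh_block", "fh_block", "bh_loop"],
    ["fh_drive", "bh_block", "fh_loop", "bh_loop", "fh_push", "fh_block", "fh_push", "bh_push", "bh_block", "fh_push"]
  ]
}
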