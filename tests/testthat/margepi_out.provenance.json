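{
  "tool": "margepi",
  "version": "0.1.0",
  "subcommand": "frobnicate",
  "options": [],
  "time": "2026-09-19T17:40:52+0000"
}
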