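{
  "version": "ukall_heh_v1",
  "description": "UKALL-HeH four-trisomy decision table: good risk = gain of 17 and/or 18 with neither 5 nor 20 gained; all other combinations poor risk. Keys are g5,g17,g18,g20 as 0/1.",
  "table": {
    "0,0,0,0": "PR",
    "1,0,0,0": "PR",
    "0,1,0,0": "GR",
    "1,1,0,0": "PR",
    "0,0,1,0": "GR",
    "1,0,1,0": "PR",
    "0,1,1,0": "GR",
    "1,1,1,0": "PR",
    "0,0,0,1": "PR",
    "1,0,0,1": "PR",
    "0,1,0,1": "PR",
    "1,1,0,1": "PR",
    "0,0,1,1": "PR",
    "1,0,1,1": "PR",
    "0,1,1,1": "PR",
    "1,1,1,1": "PR"
  }
}
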