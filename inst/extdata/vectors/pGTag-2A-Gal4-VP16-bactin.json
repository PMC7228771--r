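{
  "name": "pGTag-2A-Gal4/VP16-b-actin",
  "note": "SYNTHETIC PLACEHOLDER backbone/cargo sequences. Replace with the deposited Addgene map for real designs; tests and examples never depend on these payloads.",
  "backbone": "CGAATTACTACCGAGATAGGGGGGTGTTGAACACCGTAGCGTGGTGTGACGGTAACCGTATGGCGGACTAAGCTGCGAATCAGTATAGGTGTCCATTAGTGAAAGCATTTCTCCAATTGACCATTCGATGTCATATTTCGTCTCCCTGTTATCGGGTTTAGTACTCTCCACTTCTCAGAGCTAAGACGAAGCGCATACTAGGGTCCAAGTATACAGGGTAGTTTTTCCGGGGGGGGTTGG",
  "cargo": "TGTCCCGTAGTTAGGTGTATCGTGGGAGTGACGCGGATGTCAATGTGGCGGGGGTCCATTACTCTTCCAATTACGGCATGATCAGAAAAACGTTAGGAGACCGAGGTGCCCTAAGGTAAA",
  "buffer": {
    "five_prime": "AAA",
    "three_prime": "AAA"
  },
  "ug_orientation": {
    "five_prime": "pam_in",
    "three_prime": "pam_in"
  },
  "cargo_junction_phase": 0
}
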