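# Domain definition for mature MMP-2 (author residue numbering, inclusive).
# The fibronectin insert lies within the catalytic domain; it is listed after
# Cat so its label wins over the overlapping range, and the Cat-with-Fib union
# is recoverable as "domain Cat or domain Fib".
domains:
  Cat: [110, 445]
  Fib: [217, 393]
  Lnk: [446, 460]
  Hpx: [461, 660]
ion_names: [ZN, CA]
equilibration_ns: 200
stride_ns: 0.1
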