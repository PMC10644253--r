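{
  "Fc5": 8,
  "Fc3": 8,
  "Fc1": 8,
  "Fcz": 7,
  "Fc2": 6,
  "Fc4": 5,
  "Fc6": 5,
  "C5": 1,
  "C3": 1,
  "C1": 8,
  "Cz": 7,
  "C2": 5,
  "C4": 5,
  "C6": 5,
  "Cp5": 1,
  "Cp3": 1,
  "Cp1": 2,
  "Cpz": 2,
  "Cp2": 4,
  "Cp4": 4,
  "Cp6": 4,
  "Fp1": 7,
  "Fpz": 7,
  "Fp2": 6,
  "Af7": 7,
  "Af3": 7,
  "Afz": 6,
  "Af4": 6,
  "Af8": 6,
  "F7": 8,
  "F5": 8,
  "F3": 8,
  "F1": 7,
  "Fz": 7,
  "F2": 6,
  "F4": 6,
  "F6": 6,
  "F8": 5,
  "Ft7": 8,
  "Ft8": 5,
  "T7": 1,
  "T8": 5,
  "T9": 1,
  "T10": 4,
  "Tp7": 1,
  "Tp8": 4,
  "P7": 1,
  "P5": 2,
  "P3": 2,
  "P1": 2,
  "Pz": 3,
  "P2": 3,
  "P4": 4,
  "P6": 4,
  "P8": 4,
  "Po7": 2,
  "Po3": 2,
  "Poz": 3,
  "Po4": 3,
  "Po8": 3,
  "O1": 2,
  "Oz": 3,
  "O2": 3,
  "Iz": 3
}
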