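{
  "56": ["Fc5", "Fc3", "Fc1", "Fcz", "Fc2", "Fc4", "Fc6", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "Cp5", "Cp3", "Cp1", "Cpz", "Cp2", "Cp4", "Cp6", "Fp1", "Fpz", "Fp2", "Af7", "Af3", "Afz", "Af4", "Af8", "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8", "Ft7", "Ft8", "T7", "T8", "T9", "T10", "Tp7", "Tp8", "P7", "P1", "P2", "P6", "Po7", "Poz", "Po8", "O1", "O2", "Iz"],
  "48": ["Fc5", "Fc3", "Fc1", "Fcz", "Fc2", "Fc4", "Fc6", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "Cp5", "Cp3", "Cp4", "Cp6", "Fp1", "Fpz", "Fp2", "Af7", "Afz", "Af8", "F7", "F5", "F3", "F1", "F2", "F8", "Ft7", "Ft8", "T7", "T8", "T9", "T10", "Tp7", "Tp8", "P7", "P1", "P2", "P6", "Po7", "Poz", "Po8", "O1", "O2", "Iz"],
  "40": ["Fc5", "Fc3", "Fc1", "Fc2", "Fc4", "Fc6", "C5", "C3", "Cz", "C2", "C4", "C6", "Cp5", "Fp1", "Fpz", "Fp2", "Af7", "Afz", "Af8", "F7", "F1", "F2", "F8", "Ft7", "Ft8", "T7", "T8", "T9", "T10", "Tp7", "Tp8", "P7", "P1", "P2", "P6", "Po7", "Poz", "O1", "O2", "Iz"],
  "32": ["Fc5", "Fc3", "Fc2", "Fc6", "C5", "C3", "Cz", "C4", "Cp5", "Fp1", "Fpz", "Fp2", "Af7", "Afz", "Af8", "F7", "F1", "F2", "F8", "Ft7", "Ft8", "T9", "T10", "Tp8", "P7", "P1", "P2", "P6", "Poz", "O1", "O2", "Iz"],
  "24": ["Fc5", "Fc6", "C3", "Cz", "C4", "Cp5", "Fp1", "Fpz", "Fp2", "Af7", "Af8", "F7", "F1", "F2", "F8", "T9", "T10", "Tp8", "P7", "P1", "P2", "P6", "O2", "Iz"],
  "16": ["Fc5", "Fc6", "C3", "Cz", "C4", "Fpz", "Af7", "Af8", "F1", "F2", "T9", "T10", "P7", "P1", "P6", "Iz"]
}
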