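analytes:
- name: NAM
  formula: C6H6N2O
  retention_time: 1.0
  rt_sd: 0.0
  parent_mz: 123.0
  quant_mz: 79.7
  qual_mz: 96.0
  cone_voltage: 38.0
  collision_energy: 18.0
  istd: NAM
  quantified: yes
- name: NCA
  formula: C6H5NO2
  retention_time: 1.6
  rt_sd: 0.2
  parent_mz: 124.0
  quant_mz: 80.2
  qual_mz: 53.0
  cone_voltage: 38.0
  collision_energy: 18.0
  istd: NAM
  quantified: yes
- name: 1-mNAM
  formula: C7H9N2O
  retention_time: 2.5
  rt_sd: 0.2
  parent_mz: 137.0
  quant_mz: 78.0
  qual_mz: 108.1
  cone_voltage: 24.0
  collision_energy: 22.0
  istd: NR
  quantified: yes
- name: NR
  formula: C11H15N2O5
  retention_time: 2.9
  rt_sd: 0.1
  parent_mz: 255.9
  quant_mz: 123.7
  qual_mz: 80.2
  cone_voltage: 14.0
  collision_energy: 8.0
  istd: NR
  quantified: yes
- name: FAD
  formula: C27H33N9O15P2
  retention_time: 3.2
  rt_sd: 0.5
  parent_mz: 786.1
  quant_mz: 348.0
  qual_mz: 439.1
  cone_voltage: 20.0
  collision_energy: 22.0
  istd: FAD
  quantified: yes
- name: NADH
  formula: C21H29N7O14P2
  retention_time: 3.7
  rt_sd: 0.4
  parent_mz: 666.1
  quant_mz: 649.0
  qual_mz: 514.1
  cone_voltage: 20.0
  collision_energy: 17.0
  istd: NADH
  quantified: yes
- name: ADPR
  formula: C15H23N5O14P2
  retention_time: 3.8
  rt_sd: 0.3
  parent_mz: 560.1
  quant_mz: 136.1
  qual_mz: 348.1
  cone_voltage: 26.0
  collision_energy: 32.0
  istd: NADH
  quantified: yes
- name: NAD+
  formula: C21H27N7O14P2
  retention_time: 4.2
  rt_sd: 0.3
  parent_mz: 664.1
  quant_mz: 428.0
  qual_mz: 524.0
  cone_voltage: 20.0
  collision_energy: 26.0
  istd: NAD+
  quantified: yes
- name: NAAD
  formula: C21H26N6O15P2
  retention_time: 4.5
  rt_sd: 0.1
  parent_mz: 665.2
  quant_mz: 136.1
  qual_mz: 428.1
  cone_voltage: 42.0
  collision_energy: 36.0
  istd: NAD+
  quantified: no
- name: NMN
  formula: C11H15N2O8P
  retention_time: 4.9
  rt_sd: 0.2
  parent_mz: 335.0
  quant_mz: 123.1
  qual_mz: 97.0
  cone_voltage: 22.0
  collision_energy: 14.0
  istd: NAMN
  quantified: yes
- name: NAMN
  formula: C11H14NO9P
  retention_time: 5.1
  rt_sd: 0.2
  parent_mz: 336.0
  quant_mz: 124.1
  qual_mz: 97.0
  cone_voltage: 22.0
  collision_energy: 12.0
  istd: NAMN
  quantified: yes
- name: NADPH
  formula: C21H30N7O17P3
  retention_time: 5.1
  rt_sd: 0.2
  parent_mz: 746.1
  quant_mz: 729.0
  qual_mz: 302.0
  cone_voltage: 20.0
  collision_energy: 17.0
  istd: NADPH
  quantified: yes
- name: NADP+
  formula: C21H28N7O17P3
  retention_time: 5.5
  rt_sd: 0.2
  parent_mz: 744.1
  quant_mz: 604.0
  qual_mz: 508.0
  cone_voltage: 20.0
  collision_energy: 20.0
  istd: NADP+
  quantified: yes
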