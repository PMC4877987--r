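COG_SC_01
COG_SC_02
COG_SC_03
COG_SC_04
COG_SC_05
COG_SC_06
COG_SC_07
COG_SC_08
COG_SC_09
COG_SC_10
COG_SC_11
COG_SC_12
COG_SC_13
COG_SC_14
COG_SC_15
COG_SC_16
COG_SC_17
COG_SC_18
COG_SC_19
COG_SC_20
COG_SC_21
COG_SC_22
COG_SC_23
COG_SC_24
COG_SC_25
COG_SC_26
COG_SC_27
COG_SC_28
COG_SC_29
COG_SC_30
COG_SC_31
COG_SC_32
COG_SC_33
COG_SC_34
COG_SC_35
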