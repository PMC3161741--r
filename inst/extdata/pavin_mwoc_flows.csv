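flow_id,value
CgppTOph3,261.63
CgppTOph2,33.94
CgppTOph1,64.96
Cph3TOres,100.49
Cph3TOdoc,55.57
Cph3TOmic,14.86
Cph3TOmes,5.94
Cph3TOdet,29.75
Cph3TOlos,55.03
Cph2TOres,4
Cph2TOdoc,6.03
Cph2TOmic,14.77
Cph2TOmes,6.62
Cph2TOlos,1.28
Cph2TOdet,1.25
Cph1TOres,10.88
Cph1TOdoc,16.41
Cph1TOhnf,31.98
Cph1TOmic,4.18
Cph1TOmes,1.51
CbacTOres,71.75
CbacTOhnf,67.24
CbacTOmes,6.88
CbacTOmic,4.09
CbacTOdoc,9.9
CbacTOdet,1.88
ChnfTOres,25.1
ChnfTOdoc,21.91
ChnfTOmic,29.61
ChnfTOmes,10.07
ChnfTOdet,12.54
CmicTOres,16.94
CmicTOdoc,13.94
CmicTOmes,24.57
CmicTOdet,9.66
CmicTOlos,2.4
CmesTOres,18.29
CmesTOdoc,14.98
CmesTOdet,7.77
CmesTOlos,17.1
CdocTObac,161.75
CdetTOdoc,23.01
CdetTOmes,2.55
CdetTOlos,37.3
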