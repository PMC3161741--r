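flow_id,value
CgppTOph3,267.8
CgppTOph2,35.27
CgppTOph1,57.47
Cph3TOres,101.67
Cph3TOdoc,56.11
Cph3TOmic,11.01
Cph3TOmes,6.13
Cph3TOspg,57.44
Cph3TOdet,9.36
Cph3TOlos,26.07
Cph2TOres,2.53
Cph2TOdoc,3.75
Cph2TOmic,18.24
Cph2TOmes,9.71
Cph2TOlos,0.52
Cph2TOdet,0.51
Cph1TOres,11.16
Cph1TOdoc,13.2
Cph1TOhnf,25.85
Cph1TOmic,5.1
Cph1TOmes,2.16
CbacTOres,73.27
CbacTOhnf,61.59
CbacTOmes,10.87
CbacTOmic,5.98
CbacTOdoc,9.9
CbacTOdet,1.67
ChnfTOres,29.25
ChnfTOdoc,23.1
ChnfTOmic,14.41
ChnfTOmes,10.27
ChnfTOdet,10.39
CmicTOres,21.87
CmicTOdoc,16.27
CmicTOmes,38.14
CmicTOdet,10.44
CmicTOlos,1.38
CmesTOres,24.16
CmesTOdoc,17.88
CmesTOdet,10.7
CmesTOlos,39.25
CspgTOres,6.9
CspgTOzsp,46.79
CspgTOdet,0.86
CspgTOlos,2.89
CzspTOres,5.92
CzspTOmic,33.34
CzspTOmes,6.63
CzspTOdet,0.9
CdocTObac,163.27
CdetTOdoc,23.06
CdetTOmes,8.07
CdetTOlos,14
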