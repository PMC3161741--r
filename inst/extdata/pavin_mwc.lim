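# Lake Pavin spring 2007 pelagic food web, model with chytrids (MWC)
# Steady-state carbon flows, mg C m-2 d-1. Mass-balance equalities are
# generated from the flow topology (one per compartment) on parse.
NAME pavin_mwc

COMPARTMENTS
ph1 living Picophytoplankton (0.2-2 um)
ph2 living Nanophytoplankton (2-20 um)
ph3 living Microphytoplankton (20-150 um)
bac living Heterotrophic bacteria
hnf living Heterotrophic nanoflagellates
mic living Microzooplankton
mes living Mesozooplankton
spg living Chytrid sporangia (host-attached)
zsp living Chytrid zoospores (free-living)
det nonliving Detritus
doc nonliving Dissolved organic carbon

FLOWS
CgppTOph3: gpp -> ph3 [import]
CgppTOph2: gpp -> ph2 [import]
CgppTOph1: gpp -> ph1 [import]
Cph3TOres: ph3 -> res [dissipation]
Cph3TOdoc: ph3 -> doc [internal]
Cph3TOmic: ph3 -> mic [internal]
Cph3TOmes: ph3 -> mes [internal]
Cph3TOspg: ph3 -> spg [internal]
Cph3TOdet: ph3 -> det [internal]
Cph3TOlos: ph3 -> los [export]
Cph2TOres: ph2 -> res [dissipation]
Cph2TOdoc: ph2 -> doc [internal]
Cph2TOmic: ph2 -> mic [internal]
Cph2TOmes: ph2 -> mes [internal]
Cph2TOlos: ph2 -> los [export]
Cph2TOdet: ph2 -> det [internal]
Cph1TOres: ph1 -> res [dissipation]
Cph1TOdoc: ph1 -> doc [internal]
Cph1TOhnf: ph1 -> hnf [internal]
Cph1TOmic: ph1 -> mic [internal]
Cph1TOmes: ph1 -> mes [internal]
CbacTOres: bac -> res [dissipation]
CbacTOhnf: bac -> hnf [internal]
CbacTOmes: bac -> mes [internal]
CbacTOmic: bac -> mic [internal]
CbacTOdoc: bac -> doc [internal]
CbacTOdet: bac -> det [internal]
ChnfTOres: hnf -> res [dissipation]
ChnfTOdoc: hnf -> doc [internal]
ChnfTOmic: hnf -> mic [internal]
ChnfTOmes: hnf -> mes [internal]
ChnfTOdet: hnf -> det [internal]
CmicTOres: mic -> res [dissipation]
CmicTOdoc: mic -> doc [internal]
CmicTOmes: mic -> mes [internal]
CmicTOdet: mic -> det [internal]
CmicTOlos: mic -> los [export]
CmesTOres: mes -> res [dissipation]
CmesTOdoc: mes -> doc [internal]
CmesTOdet: mes -> det [internal]
CmesTOlos: mes -> los [export]
CspgTOres: spg -> res [dissipation]
CspgTOzsp: spg -> zsp [internal]
CspgTOdet: spg -> det [internal]
CspgTOlos: spg -> los [export]
CzspTOres: zsp -> res [dissipation]
CzspTOmic: zsp -> mic [internal]
CzspTOmes: zsp -> mes [internal]
CzspTOdet: zsp -> det [internal]
CdocTObac: doc -> bac [internal]
CdetTOdoc: det -> doc [internal]
CdetTOmes: det -> mes [internal]
CdetTOlos: det -> los [export]

EQUALITIES
# measured during spring blooms in Lake Pavin (14C, thymidine, TEM)
CgppTOph1 + CgppTOph2 + CgppTOph3 = 360.54                              # total gross primary production
CgppTOph1 + CgppTOph2 + CgppTOph3 - Cph1TOres - Cph2TOres - Cph3TOres = 245.17  # total net primary production
CdocTObac - CbacTOres = 90                                              # net bacterial production
CbacTOdoc = 9.90                                                        # viral lysis of bacteria

CONSTRAINTS
# gross primary production partitioning between size fractions,
# bounded by the spring 2007 biomass-fraction range of each class
0.45*CgppTOph3 - 0.55*CgppTOph1 - 0.55*CgppTOph2 >= 0
0.10*CgppTOph3 - 0.90*CgppTOph1 - 0.90*CgppTOph2 <= 0
0.96*CgppTOph2 - 0.04*CgppTOph1 - 0.04*CgppTOph3 >= 0
0.75*CgppTOph2 - 0.25*CgppTOph1 - 0.25*CgppTOph3 <= 0
0.95*CgppTOph1 - 0.05*CgppTOph2 - 0.05*CgppTOph3 >= 0
0.70*CgppTOph1 - 0.30*CgppTOph2 - 0.30*CgppTOph3 <= 0
# ph1 physiology
Cph1TOres - 0.05*CgppTOph1 >= 0
Cph1TOres - 0.55*CgppTOph1 <= 0
Cph1TOdoc - 0.02*CgppTOph1 >= 0
Cph1TOdoc - 0.55*CgppTOph1 <= 0
# ph2 physiology
Cph2TOres - 0.05*CgppTOph2 >= 0
Cph2TOres - 0.55*CgppTOph2 <= 0
Cph2TOdoc - 0.02*CgppTOph2 >= 0
Cph2TOdoc - 0.55*CgppTOph2 <= 0
# ph3 physiology
Cph3TOres - 0.05*CgppTOph3 >= 0
Cph3TOres - 0.55*CgppTOph3 <= 0
Cph3TOdoc - 0.02*CgppTOph3 >= 0
Cph3TOdoc - 0.55*CgppTOph3 <= 0
# bacteria: growth/respiration bounds on DOC uptake, attached fraction
CbacTOres - 0.20*CdocTObac >= 0
CbacTOres - 0.80*CdocTObac <= 0
CbacTOdet - 0.10*CdocTObac <= 0
# minimum bacterivory by heterotrophic nanoflagellates (in situ estimate)
CbacTOhnf >= 50
# hnf physiology (respiration, egestion, excretion bounds)
ChnfTOres - 0.20*Cph1TOhnf - 0.20*CbacTOhnf >= 0
ChnfTOres - 0.80*Cph1TOhnf - 0.80*CbacTOhnf <= 0
ChnfTOdet - 0.06*Cph1TOhnf - 0.06*CbacTOhnf >= 0
ChnfTOdet - 0.50*Cph1TOhnf - 0.50*CbacTOhnf <= 0
ChnfTOdoc - ChnfTOres <= 0
ChnfTOdoc - 0.10*ChnfTOres >= 0
# mic physiology (respiration, egestion, excretion bounds)
CmicTOres - 0.20*Cph3TOmic - 0.20*Cph2TOmic - 0.20*Cph1TOmic - 0.20*CbacTOmic - 0.20*ChnfTOmic - 0.20*CzspTOmic >= 0
CmicTOres - 0.80*Cph3TOmic - 0.80*Cph2TOmic - 0.80*Cph1TOmic - 0.80*CbacTOmic - 0.80*ChnfTOmic - 0.80*CzspTOmic <= 0
CmicTOdet - 0.06*Cph3TOmic - 0.06*Cph2TOmic - 0.06*Cph1TOmic - 0.06*CbacTOmic - 0.06*ChnfTOmic - 0.06*CzspTOmic >= 0
CmicTOdet - 0.50*Cph3TOmic - 0.50*Cph2TOmic - 0.50*Cph1TOmic - 0.50*CbacTOmic - 0.50*ChnfTOmic - 0.50*CzspTOmic <= 0
CmicTOdoc - CmicTOres <= 0
CmicTOdoc - 0.10*CmicTOres >= 0
# mes physiology (respiration, egestion, excretion bounds)
CmesTOres - 0.20*Cph3TOmes - 0.20*Cph2TOmes - 0.20*Cph1TOmes - 0.20*CbacTOmes - 0.20*ChnfTOmes - 0.20*CmicTOmes - 0.20*CzspTOmes - 0.20*CdetTOmes >= 0
CmesTOres - 0.80*Cph3TOmes - 0.80*Cph2TOmes - 0.80*Cph1TOmes - 0.80*CbacTOmes - 0.80*ChnfTOmes - 0.80*CmicTOmes - 0.80*CzspTOmes - 0.80*CdetTOmes <= 0
CmesTOdet - 0.06*Cph3TOmes - 0.06*Cph2TOmes - 0.06*Cph1TOmes - 0.06*CbacTOmes - 0.06*ChnfTOmes - 0.06*CmicTOmes - 0.06*CzspTOmes - 0.06*CdetTOmes >= 0
CmesTOdet - 0.50*Cph3TOmes - 0.50*Cph2TOmes - 0.50*Cph1TOmes - 0.50*CbacTOmes - 0.50*ChnfTOmes - 0.50*CmicTOmes - 0.50*CzspTOmes - 0.50*CdetTOmes <= 0
CmesTOdoc - CmesTOres <= 0
CmesTOdoc - 0.10*CmesTOres >= 0
# preferential ingestion (prey-size dominance during spring 2007)
CmicTOmes - ChnfTOmes >= 0
Cph2TOmic - Cph1TOmic >= 0
# chytrid life cycle: low metabolic losses, zoospores grazed mainly by mic
CspgTOres - 0.20*Cph3TOspg <= 0
CzspTOres - 0.20*CspgTOzsp <= 0
CzspTOmic - 2*CzspTOmes >= 0
CspgTOzsp >= 15
CspgTOdet - 0.10*Cph3TOspg <= 0
CzspTOdet - 0.10*CspgTOzsp <= 0
CspgTOlos - 0.10*Cph3TOspg <= 0
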