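# Default trait table for the two phytoplankton size classes.
#
# Format: INI-style blocks. `[shared]` holds parameters common to both
# classes; `[small]` / `[large]` override or extend them per class.
# All quotas are normalized per mole cellular carbon (Q_C = 1).
#
# Units are given per key. "d" = day.

[shared]
# --- macromolecular allocation coefficients ---
A_RNA_P      = 0.008    # RNA-P per protein-C per growth rate, mol P (mol C)^-1 d
Q_P_min_RNA  = 6.0e-4   # minimum RNA phosphorus, mol P (mol C)^-1
A_Pho        = 2.0      # photosynthetic protein C per chlorophyll C, mol C (mol C)^-1
A_Bio        = 0.15     # biosynthetic protein C per growth rate, mol C d (mol C)^-1
Q_C_Pro_Other = 0.24    # other (constitutive) protein, mol C (mol C)^-1
Q_C_DNA      = 0.001    # DNA carbon, mol C (mol C)^-1
Q_C_Other    = 0.30     # other carbon (carbohydrate, lipid, wall), mol C (mol C)^-1
Q_P_Other    = 0.0015   # other phosphorus (non-thylakoid lipid etc.), mol P (mol C)^-1
A_Pho_PChl   = 0.03     # thylakoid P per chlorophyll C, mol P (mol C)^-1
A_Pho_Fe     = 0.001    # photosystem Fe per chlorophyll C, mol Fe (mol C)^-1
E            = 0.2      # growth-dependent respiration, dimensionless
m            = 0.2      # maintenance respiration, d^-1

# --- fixed macromolecular elemental ratios (mol/mol) ---
Y_Pro_NC     = 0.26     # protein N:C
Y_RNA_NP     = 3.8      # RNA N:P
Y_RNA_CP     = 9.5      # RNA C:P
Y_DNA_NC     = 0.39     # DNA N:C
Y_DNA_PC     = 0.103    # DNA P:C
Y_Chl_NC     = 0.0727   # chlorophyll a N:C (4/55)
Y_Plip_CP    = 40.0     # thylakoid phospholipid C:P
Y_Nsto_CN    = 2.0      # N-storage C:N (cyanophycin-like)

# --- exudation and mortality ---
tau_Exu_N    = 0.05     # excess-N exudation timescale, d
tau_Exu_P    = 0.05     # excess-P exudation timescale, d
tau_Exu_Fe   = 0.05     # excess-Fe exudation timescale, d
m_l          = 0.1      # linear mortality (sinking + maintenance losses), d^-1
m_q          = 0.5      # quadratic mortality (implicit grazing), (mmol C m^-3)^-1 d^-1

[small]
# picocyanobacteria analogue: gleaner (high affinity, low maximum rates)
A_I          = 0.025    # light-response coefficient, (umol m^-2 s^-1)^-1; low-light specialist
v_I_max      = 40.0     # max chlorophyll-specific photosynthesis, mol C (mol C in Chl)^-1 d^-1
V_max_N      = 0.30     # max N uptake, mol N (mol C)^-1 d^-1
V_max_P      = 0.025     # max P uptake, mol P (mol C)^-1 d^-1
V_max_Fe     = 1.0e-4   # max Fe uptake, mol Fe (mol C)^-1 d^-1
K_N          = 0.15     # NO3 half-saturation, mmol m^-3
K_P          = 0.05    # PO4 half-saturation, mmol m^-3
K_Fe         = 1.5e-4   # Fe half-saturation, mmol m^-3
Q_P_max      = 0.012    # maximum P quota (structure + storage), mol P (mol C)^-1
Q_Fe_max     = 8.0e-5   # maximum Fe quota, mol Fe (mol C)^-1
Q_N_Sto_max  = 0.03     # maximum N storage, mol N (mol C)^-1

[large]
# eukaryote analogue: opportunist (high maximum rates, high P storage)
A_I          = 0.006    # light-response coefficient, (umol m^-2 s^-1)^-1
v_I_max      = 120.0
V_max_N      = 0.50
V_max_P      = 0.08
V_max_Fe     = 1.5e-4
K_N          = 0.75
K_P          = 0.3
K_Fe         = 4.0e-4
Q_P_max      = 0.028
Q_Fe_max     = 1.5e-4
Q_N_Sto_max  = 0.04
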