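# The integrated macrophage polarization network: IFN-gamma (M1), IL-4 (M2)
# and hypoxia (HIF) pathways with SOCS negative feedback, STAT antagonism,
# one-step AKT activation, a lumped PHD/FIH oxygen sensor and direct
# miR-mRNA binding. This is a synthetic transcription: the topology follows
# the published mechanistic description of the pathways, while the kinetic
# parameter values and copy numbers are this package's own nominal set
# (provenance "synthetic"), chosen to give a plausible unpolarized baseline
# and qualitatively correct stimulus responses.
#
# State units: molecules per cell (molecules per cell-equivalent medium
# volume for extracellular species); time in hours.

# Reaction shorthand used only by the builder below. `num` pins the
# reaction number (and so its parameter labels k<num>/kf<num>/ka<num>...)
# where a label is referenced elsewhere (perturbation presets, sensitivity
# label lists); unnumbered reactions are assigned the free numbers in
# definition order.
.mk_rxn <- function(kind, vals, num = NA, reactants = c(), products = c(),
                    modifiers = character(), ann = "") {
  list(num = num, kind = kind, vals = vals, reactants = reactants,
       products = products, modifiers = modifiers, ann = ann)
}

.macro_species <- function() {
  s <- function(id, group, comp = "cytoplasm", init = 0, buf = FALSE)
    mp_species(id, group = group, compartment = comp, initial = init,
               buffered = buf)
  rbind(
    # --- IFN-gamma ligand (autocrine-capable) ---
    s("IFNg_c", "IFNg", init = 10),
    s("IFNg", "IFNg", "extracellular", init = 100),
    # --- IFN-gamma receptor module (no internalization) ---
    s("R_I", "IFNGR", "membrane", init = 2000),
    s("R_I_lig", "IFNGR", "membrane"),
    s("R_I_act", "IFNGR", "membrane"),
    s("R_I_S1", "IFNGR", "membrane"),
    s("R_I_S3", "IFNGR", "membrane"),
    # --- STAT1 cascade ---
    s("STAT1c", "STAT1", init = 2e5),
    s("S1dock", "STAT1", "membrane"),
    s("pSTAT1c", "STAT1"),
    s("pSTAT1d_c", "STAT1"),
    s("pSTAT1d_n", "STAT1", "nucleus"),
    # --- IRF-1 ---
    s("IRF1_mRNA", "IRF1", init = 20),
    s("IRF1", "IRF1", init = 2000),
    # --- SOCS feedback ---
    s("SOCS1_mRNA", "SOCS1", init = 5),
    s("SOCS1", "SOCS1", init = 100),
    s("SOCS3", "SOCS3", init = 100),
    # --- M1 markers ---
    s("iNOS_mRNA", "iNOS", init = 10),
    s("iNOS", "iNOS", init = 500),
    s("TNFa_mRNA", "TNFa", init = 10),
    s("TNFa_c", "TNFa", init = 100),
    s("TNFa", "TNFa", "extracellular", init = 500),
    s("IL12_c", "IL12", init = 100),
    s("IL12", "IL12", "extracellular", init = 500),
    s("CXCL9_c", "CXCL9", init = 100),
    s("CXCL9", "CXCL9", "extracellular", init = 500),
    s("CXCL10_mRNA", "CXCL10", init = 20),
    s("CXCL10", "CXCL10", "extracellular", init = 500),
    # --- miR-3473b / PTEN / AKT (IFN-gamma counter-regulation of AKT) ---
    s("miR3473b", "miR3473b", init = 2000),
    s("PTEN_mRNA", "PTEN", init = 50),
    s("PTEN_mRNA_miR", "PTEN", init = 50),
    s("PTEN", "PTEN", init = 1e4),
    # --- miR-93 / IRF-9 / IRG-1 / itaconate / ROS ---
    s("miR93", "miR93", init = 2000),
    s("IRF9_mRNA", "IRF9", init = 50),
    s("IRF9_mRNA_miR", "IRF9", init = 50),
    s("IRF9", "IRF9", init = 2000),
    s("IRG1", "IRG1", init = 500),
    s("ITA", "ITA", init = 1e4),
    s("ROS", "ROS", init = 1000),
    # --- IL-4 ligand ---
    s("IL4_c", "IL4", init = 10),
    s("IL4", "IL4", "extracellular", init = 100),
    # --- IL-4 receptor module (with internalization and recycling) ---
    s("R_4", "IL4R", "membrane", init = 2000),
    s("R_4_lig", "IL4R", "membrane"),
    s("R_4_act", "IL4R", "membrane"),
    s("R_4_int", "IL4R"),
    s("R_4_S1", "IL4R", "membrane"),
    s("R_4_S3", "IL4R", "membrane"),
    s("R_4_int_S1", "IL4R"),
    s("R_4_int_S3", "IL4R"),
    # --- STAT6 cascade + STAT1/STAT6 nuclear sequestration ---
    s("STAT6c", "STAT6", init = 2e5),
    s("S6dock", "STAT6", "membrane"),
    s("pSTAT6c", "STAT6"),
    s("pSTAT6d_c", "STAT6"),
    s("pSTAT6d_n", "STAT6", "nucleus"),
    s("S1S6_n", "STAT6", "nucleus"),
    # --- M2 transcription factors and markers ---
    s("IRF4", "IRF4", init = 2000),
    s("PPARg", "PPARg", init = 2000),
    s("AKT", "AKT", init = 1e5),
    s("pAKT", "AKT", init = 1000),
    s("Arg1_mRNA", "Arg1", init = 20),
    s("Arg1", "Arg1", init = 2000),
    s("IL10_c", "IL10", init = 100),
    s("IL10", "IL10", "extracellular", init = 500),
    s("VEGF_c", "VEGF", init = 100),
    s("VEGF", "VEGF", "extracellular", init = 500),
    # --- oxygen sensing / HIF module ---
    s("O2", "O2", "extracellular", init = 2.1e5, buf = TRUE),
    s("HIF1a_mRNA", "HIF1a", init = 50),
    s("HIF1a_mRNA_miR", "HIF1a", init = 50),
    s("HIF1a", "HIF1a", init = 1000),
    s("HIF1a_OH", "HIF1a", init = 500),
    s("HIF1a_n", "HIF1a", "nucleus", init = 200),
    s("HIF2a", "HIF2a", init = 1000),
    s("HIF2a_OH", "HIF2a", init = 500),
    s("HIF2a_n", "HIF2a", "nucleus", init = 200),
    s("HIF1b", "HIF1b", "nucleus", init = 1e4),
    s("PHD", "PHD", init = 5000),
    s("PHD_act", "PHD", init = 5000),
    s("PHD_ROS", "PHD", init = 100),
    s("HIF1_n", "HIF1", "nucleus", init = 100),
    s("HIF2_n", "HIF2", "nucleus", init = 100))
}

.macro_reactions <- function() {
  r <- .mk_rxn
  list(
    ## IFN-gamma ligand -------------------------------------------------
    r("hill_activation", c(2000, 500), num = 127,
      products = c(IFNg_c = 1), modifiers = "HIF1_n",
      ann = "HIF-1 driven IFN-gamma production (hypoxic autocrine loop)"),
    r("mass_action_irreversible", 2, reactants = c(IFNg_c = 1),
      products = c(IFNg = 1), ann = "IFN-gamma secretion"),
    r("mass_action_irreversible", 0.2, reactants = c(IFNg = 1),
      ann = "extracellular IFN-gamma consumption (lumped cell uptake)"),
    ## IFN-gamma receptor -----------------------------------------------
    r("mass_action_irreversible", 100, products = c(R_I = 1),
      ann = "IFN-gamma receptor/JAK synthesis"),
    r("mass_action_irreversible", 0.05, reactants = c(R_I = 1),
      ann = "receptor turnover"),
    r("mass_action_reversible", c(1e-5, 0.1), num = 17,
      reactants = c(IFNg = 1, R_I = 1), products = c(R_I_lig = 1),
      ann = "IFN-gamma receptor ligation"),
    r("mass_action_reversible", c(10, 0.5), num = 42,
      reactants = c(R_I_lig = 1), products = c(R_I_act = 1),
      ann = "JAK transphosphorylation: active IFN-gamma receptor complex"),
    r("mass_action_irreversible", 0.1, reactants = c(R_I_act = 1),
      products = c(R_I = 1),
      ann = "complex turnover: receptor recycled, bound ligand degraded"),
    r("mass_action_reversible", c(1e-3, 0.2),
      reactants = c(SOCS1 = 1, R_I_act = 1), products = c(R_I_S1 = 1),
      ann = "SOCS1 binds active IFN-gamma receptor complex"),
    r("mass_action_irreversible", 1, reactants = c(R_I_S1 = 1),
      ann = "SOCS1-induced complex degradation (JAK sequestered/degraded)"),
    r("mass_action_reversible", c(5e-4, 0.2),
      reactants = c(SOCS3 = 1, R_I_act = 1), products = c(R_I_S3 = 1),
      ann = "SOCS3 sequesters active IFN-gamma receptor complex"),
    ## STAT1 cascade -----------------------------------------------------
    r("mass_action_reversible", c(2e-5, 1), num = 63,
      reactants = c(STAT1c = 1, R_I_act = 1), products = c(S1dock = 1),
      ann = "STAT1 binds activated IFN-gamma receptor complex"),
    r("mass_action_irreversible", 20, num = 33,
      reactants = c(S1dock = 1),
      products = c(pSTAT1c = 1, R_I_act = 1),
      ann = "STAT1 phosphorylation and release"),
    r("mass_action_reversible", c(2e-5, 0.2), num = 64,
      reactants = c(pSTAT1c = 2), products = c(pSTAT1d_c = 1),
      ann = "phospho-STAT1 dimerization"),
    r("mass_action_irreversible", 2, num = 45,
      reactants = c(pSTAT1d_c = 1), products = c(pSTAT1d_n = 1),
      ann = "STAT1 dimer nuclear translocation"),
    r("mass_action_irreversible", 0.6, reactants = c(pSTAT1d_n = 1),
      products = c(STAT1c = 2),
      ann = "nuclear dephosphorylation and export"),
    ## IRF-1 --------------------------------------------------------------
    r("hill_activation", c(400, 3000), num = 61,
      products = c(IRF1_mRNA = 1), modifiers = "pSTAT1d_n",
      ann = "STAT1-driven IRF-1 transcription"),
    r("mass_action_irreversible", 1, reactants = c(IRF1_mRNA = 1),
      ann = "IRF-1 transcript decay"),
    r("mass_action_irreversible", 2e-4, reactants = c(IRF1_mRNA = 1),
      modifiers = "pSTAT6d_n",
      ann = "STAT6-dependent destabilization of IRF-1 transcript"),
    r("mass_action_irreversible", 40, products = c(IRF1 = 1),
      modifiers = "IRF1_mRNA", ann = "IRF-1 translation"),
    r("mass_action_irreversible", 0.4, reactants = c(IRF1 = 1),
      ann = "IRF-1 degradation"),
    ## SOCS feedback -------------------------------------------------------
    r("hill_activation", c(60, 3000), products = c(SOCS1_mRNA = 1),
      modifiers = "pSTAT1d_n", ann = "STAT1-driven SOCS1 transcription"),
    r("mass_action_irreversible", 2, reactants = c(SOCS1_mRNA = 1),
      ann = "SOCS1 transcript decay"),
    r("mass_action_irreversible", 40, products = c(SOCS1 = 1),
      modifiers = "SOCS1_mRNA", ann = "SOCS1 translation"),
    r("mass_action_irreversible", 2, reactants = c(SOCS1 = 1),
      ann = "SOCS1 degradation (short half-life)"),
    r("hill_activation", c(2400, 3000), products = c(SOCS3 = 1),
      modifiers = "pSTAT1d_n",
      ann = "STAT1-driven SOCS3 expression (lumped)"),
    r("mass_action_irreversible", 2, reactants = c(SOCS3 = 1),
      ann = "SOCS3 degradation (short half-life)"),
    ## M1 markers ---------------------------------------------------------
    r("hill_activation", c(100, 10000), products = c(iNOS_mRNA = 1),
      modifiers = "IRF1", ann = "IRF-1 driven iNOS transcription"),
    r("hill_activation", c(100, 500), num = 77,
      products = c(iNOS_mRNA = 1), modifiers = "HIF1_n",
      ann = "HIF-1 driven iNOS transcription"),
    r("mass_action_irreversible", 1, reactants = c(iNOS_mRNA = 1),
      ann = "iNOS transcript decay"),
    r("mass_action_irreversible", 10, products = c(iNOS = 1),
      modifiers = "iNOS_mRNA", ann = "iNOS translation"),
    r("mass_action_irreversible", 0.3, reactants = c(iNOS = 1),
      ann = "iNOS degradation"),
    r("hill_activation", c(200, 3000), products = c(TNFa_mRNA = 1),
      modifiers = "pSTAT1d_n", ann = "STAT1-driven TNF-alpha transcription"),
    r("mass_action_irreversible", 1, reactants = c(TNFa_mRNA = 1),
      ann = "TNF-alpha transcript decay"),
    r("mass_action_irreversible", 10, products = c(TNFa_c = 1),
      modifiers = "TNFa_mRNA", ann = "TNF-alpha translation"),
    r("mass_action_irreversible", 2, reactants = c(TNFa_c = 1),
      products = c(TNFa = 1), ann = "TNF-alpha secretion"),
    r("mass_action_irreversible", 0.2, reactants = c(TNFa = 1),
      ann = "secreted TNF-alpha clearance"),
    r("hill_activation", c(600, 3000), products = c(IL12_c = 1),
      modifiers = "pSTAT1d_n", ann = "STAT1-driven IL-12 synthesis"),
    r("mass_action_irreversible", 2, reactants = c(IL12_c = 1),
      products = c(IL12 = 1), ann = "IL-12 secretion"),
    r("mass_action_irreversible", 0.2, reactants = c(IL12 = 1),
      ann = "secreted IL-12 clearance"),
    r("hill_activation", c(600, 3000), num = 37,
      products = c(CXCL9_c = 1), modifiers = "pSTAT1d_n",
      ann = "STAT1-driven CXCL9 synthesis"),
    r("mass_action_irreversible", 2, reactants = c(CXCL9_c = 1),
      products = c(CXCL9 = 1), ann = "CXCL9 secretion"),
    r("mass_action_irreversible", 0.2, reactants = c(CXCL9 = 1),
      ann = "secreted CXCL9 clearance"),
    r("hill_activation", c(120, 3000), products = c(CXCL10_mRNA = 1),
      modifiers = "pSTAT1d_n", ann = "STAT1-driven CXCL10 transcription"),
    r("mass_action_irreversible", 1, reactants = c(CXCL10_mRNA = 1),
      ann = "CXCL10 transcript decay"),
    r("mass_action_irreversible", 5, products = c(CXCL10 = 1),
      modifiers = "CXCL10_mRNA", ann = "CXCL10 translation and secretion"),
    r("mass_action_irreversible", 0.2, reactants = c(CXCL10 = 1),
      ann = "secreted CXCL10 clearance"),
    ## miR-3473b / PTEN / AKT ---------------------------------------------
    r("mass_action_irreversible", 2000, products = c(miR3473b = 1),
      ann = "miR-3473b synthesis"),
    r("mass_action_irreversible", 0.5, reactants = c(miR3473b = 1),
      ann = "miR-3473b decay"),
    r("mass_action_irreversible", 5e-4, reactants = c(miR3473b = 1),
      modifiers = "pSTAT1d_n",
      ann = "IFN-gamma/STAT1-dependent miR-3473b downregulation"),
    r("mass_action_irreversible", 100, products = c(PTEN_mRNA = 1),
      ann = "PTEN transcription"),
    r("mass_action_irreversible", 0.5, reactants = c(PTEN_mRNA = 1),
      ann = "PTEN transcript decay"),
    r("mass_action_reversible", c(5e-4, 0.5),
      reactants = c(miR3473b = 1, PTEN_mRNA = 1),
      products = c(PTEN_mRNA_miR = 1),
      ann = "miR-3473b binds PTEN transcript"),
    r("mass_action_irreversible", 1, reactants = c(PTEN_mRNA_miR = 1),
      products = c(miR3473b = 1),
      ann = "miR-induced PTEN transcript degradation (miR recycled)"),
    r("mass_action_irreversible", 20, products = c(PTEN = 1),
      modifiers = "PTEN_mRNA", ann = "PTEN translation"),
    r("mass_action_irreversible", 0.2, reactants = c(PTEN = 1),
      ann = "PTEN degradation"),
    r("mass_action_irreversible", 3e-4, num = 71,
      reactants = c(AKT = 1), products = c(pAKT = 1),
      modifiers = "R_4_act",
      ann = "one-step AKT activation by active IL-4 receptor complex"),
    r("mass_action_irreversible", 5e-4, reactants = c(pAKT = 1),
      products = c(AKT = 1), modifiers = "PTEN",
      ann = "PTEN-dependent AKT deactivation"),
    ## miR-93 / IRF-9 / IRG-1 / itaconate / ROS ---------------------------
    r("mass_action_irreversible", 2000, products = c(miR93 = 1),
      ann = "miR-93 synthesis"),
    r("mass_action_irreversible", 0.2, reactants = c(miR93 = 1),
      ann = "miR-93 decay"),
    r("mass_action_irreversible", 2e-2, reactants = c(miR93 = 1),
      modifiers = "HIF1_n",
      ann = "hypoxia-dependent miR-93 downregulation"),
    r("mass_action_irreversible", 100, products = c(IRF9_mRNA = 1),
      ann = "IRF-9 transcription"),
    r("mass_action_irreversible", 0.5, reactants = c(IRF9_mRNA = 1),
      ann = "IRF-9 transcript decay"),
    r("mass_action_reversible", c(5e-4, 0.5),
      reactants = c(miR93 = 1, IRF9_mRNA = 1),
      products = c(IRF9_mRNA_miR = 1),
      ann = "miR-93 binds IRF-9 transcript"),
    r("mass_action_irreversible", 1, reactants = c(IRF9_mRNA_miR = 1),
      products = c(miR93 = 1),
      ann = "miR-induced IRF-9 transcript degradation (miR recycled)"),
    r("mass_action_irreversible", 4, products = c(IRF9 = 1),
      modifiers = "IRF9_mRNA", ann = "IRF-9 translation"),
    r("mass_action_irreversible", 0.2, reactants = c(IRF9 = 1),
      ann = "IRF-9 degradation"),
    r("hill_activation", c(0.06, 5000), products = c(IRG1 = 1),
      modifiers = c("IRF1", "IRF9"),
      ann = "IRG-1 expression potentiated by IRF-1 with IRF-9"),
    r("mass_action_irreversible", 0.3, reactants = c(IRG1 = 1),
      ann = "IRG-1 degradation"),
    r("mass_action_irreversible", 4, products = c(ITA = 1),
      modifiers = "IRG1", ann = "IRG-1 dependent itaconate production"),
    r("mass_action_irreversible", 0.2, reactants = c(ITA = 1),
      ann = "itaconate clearance"),
    r("mass_action_irreversible", 2000, products = c(ROS = 1),
      ann = "mitochondrial ROS production"),
    r("mass_action_irreversible", 2e-4, reactants = c(ROS = 1),
      modifiers = "ITA",
      ann = "itaconate-dependent limitation of ROS"),
    ## oxygen sensing / HIF module ----------------------------------------
    r("hill_activation", c(5000, 50), products = c(PHD = 1),
      modifiers = "HIF1_n",
      ann = "HIF-driven expression of the lumped PHD/FIH sensor"),
    r("mass_action_irreversible", 0.5, reactants = c(PHD = 1),
      ann = "PHD degradation"),
    r("mass_action_reversible", c(1e-10, 5), num = 52,
      reactants = c(PHD = 1, O2 = 2), products = c(PHD_act = 1),
      ann = "oxygen-dependent activation of the lumped PHD/FIH sensor (two O2-dependent hydroxylation events)"),
    r("mass_action_reversible", c(2e-5, 0.5),
      reactants = c(ROS = 1, PHD_act = 1), products = c(PHD_ROS = 1),
      ann = "ROS blocks PHD activity (sequestration)"),
    r("hill_activation", c(100, 1000), products = c(HIF1a_mRNA = 1),
      modifiers = "TNFa",
      ann = "TNF-alpha modulated HIF-1alpha transcription"),
    r("mass_action_irreversible", 0.5, reactants = c(HIF1a_mRNA = 1),
      ann = "HIF-1alpha transcript decay"),
    r("mass_action_reversible", c(5e-4, 0.5),
      reactants = c(miR93 = 1, HIF1a_mRNA = 1),
      products = c(HIF1a_mRNA_miR = 1),
      ann = "miR-93 binds HIF-1alpha transcript"),
    r("mass_action_irreversible", 1, reactants = c(HIF1a_mRNA_miR = 1),
      products = c(miR93 = 1),
      ann = "miR-induced HIF-1alpha transcript degradation"),
    r("mass_action_irreversible", 20, products = c(HIF1a = 1),
      modifiers = "HIF1a_mRNA", ann = "HIF-1alpha translation"),
    r("mass_action_irreversible", 2.5e-3, reactants = c(HIF1a = 1),
      products = c(HIF1a_OH = 1), modifiers = "PHD_act",
      ann = "PHD-dependent HIF-1alpha hydroxylation"),
    r("mass_action_irreversible", 4, reactants = c(HIF1a_OH = 1),
      ann = "ubiquitination and proteasomal degradation"),
    r("mass_action_irreversible", 0.2, reactants = c(HIF1a_OH = 1),
      products = c(HIF1a = 1), ann = "HIF-1alpha de-ubiquitination"),
    r("mass_action_irreversible", 0.2, reactants = c(HIF1a = 1),
      products = c(HIF1a_n = 1), ann = "HIF-1alpha nuclear import"),
    r("mass_action_reversible", c(2e-3, 1), num = 44,
      reactants = c(HIF1a_n = 1, HIF1b = 1), products = c(HIF1_n = 1),
      ann = "HIF-1 heterodimer assembly"),
    r("mass_action_irreversible", 0.5, reactants = c(HIF1_n = 1),
      products = c(HIF1b = 1),
      ann = "nuclear HIF-1alpha degradation, beta subunit recycled"),
    r("hill_activation", c(1200, 2000), products = c(HIF2a = 1),
      modifiers = "PPARg",
      ann = "PPAR-gamma controlled HIF-2alpha synthesis"),
    r("mass_action_irreversible", 2.5e-3, reactants = c(HIF2a = 1),
      products = c(HIF2a_OH = 1), modifiers = "PHD_act",
      ann = "PHD-dependent HIF-2alpha hydroxylation"),
    r("mass_action_irreversible", 4, reactants = c(HIF2a_OH = 1),
      ann = "HIF-2alpha proteasomal degradation"),
    r("mass_action_irreversible", 0.2, reactants = c(HIF2a = 1),
      products = c(HIF2a_n = 1), ann = "HIF-2alpha nuclear import"),
    r("mass_action_reversible", c(2e-3, 1), num = 7,
      reactants = c(HIF2a_n = 1, HIF1b = 1), products = c(HIF2_n = 1),
      ann = "HIF-2 heterodimer assembly"),
    r("mass_action_irreversible", 0.5, reactants = c(HIF2_n = 1),
      products = c(HIF1b = 1),
      ann = "nuclear HIF-2alpha degradation, beta subunit recycled"),
    ## IL-4 ligand and receptor -------------------------------------------
    r("mass_action_irreversible", 40, products = c(IL4_c = 1),
      ann = "basal IL-4 production"),
    r("mass_action_irreversible", 2, reactants = c(IL4_c = 1),
      products = c(IL4 = 1), ann = "IL-4 secretion"),
    r("mass_action_irreversible", 0.2, reactants = c(IL4 = 1),
      ann = "extracellular IL-4 consumption (lumped cell uptake)"),
    r("mass_action_irreversible", 100, products = c(R_4 = 1),
      ann = "IL-4 receptor synthesis"),
    r("mass_action_irreversible", 0.05, reactants = c(R_4 = 1),
      ann = "receptor turnover"),
    r("mass_action_reversible", c(1e-5, 0.1), num = 70,
      reactants = c(IL4 = 1, R_4 = 1), products = c(R_4_lig = 1),
      ann = "IL-4 receptor ligation"),
    r("mass_action_reversible", c(10, 0.5), num = 13,
      reactants = c(R_4_lig = 1), products = c(R_4_act = 1),
      ann = "JAK transphosphorylation: active IL-4 receptor complex"),
    r("mass_action_irreversible", 0.3, reactants = c(R_4_act = 1),
      products = c(R_4_int = 1),
      ann = "IL-4 receptor complex internalization"),
    r("mass_action_irreversible", 0.1, reactants = c(R_4_int = 1),
      products = c(R_4 = 1),
      ann = "receptor recycling, internalized ligand degraded"),
    r("mass_action_irreversible", 0.1, reactants = c(R_4_int = 1),
      ann = "lysosomal degradation of internalized complex"),
    r("mass_action_reversible", c(1e-3, 0.2),
      reactants = c(SOCS1 = 1, R_4_act = 1), products = c(R_4_S1 = 1),
      ann = "SOCS1 binds active IL-4 receptor complex"),
    r("mass_action_reversible", c(1e-4, 0.2),
      reactants = c(SOCS3 = 1, R_4_act = 1), products = c(R_4_S3 = 1),
      ann = "SOCS3 binds active IL-4 receptor complex"),
    r("mass_action_reversible", c(2e-4, 0.2),
      reactants = c(SOCS1 = 1, R_4_int = 1), products = c(R_4_int_S1 = 1),
      ann = "SOCS1 binds internalized IL-4 receptor complex"),
    r("mass_action_irreversible", 1, reactants = c(R_4_int_S1 = 1),
      ann = "SOCS1-induced degradation of internalized complex"),
    r("mass_action_reversible", c(1e-4, 0.2),
      reactants = c(SOCS3 = 1, R_4_int = 1), products = c(R_4_int_S3 = 1),
      ann = "SOCS3 sequesters internalized IL-4 receptor complex"),
    ## STAT6 cascade -------------------------------------------------------
    r("mass_action_reversible", c(2e-5, 1), num = 8,
      reactants = c(STAT6c = 1, R_4_act = 1), products = c(S6dock = 1),
      ann = "STAT6 binds activated IL-4 receptor complex"),
    r("mass_action_irreversible", 20, reactants = c(S6dock = 1),
      products = c(pSTAT6c = 1, R_4_act = 1),
      ann = "STAT6 phosphorylation and release"),
    r("mass_action_reversible", c(2e-5, 0.2), num = 95,
      reactants = c(pSTAT6c = 2), products = c(pSTAT6d_c = 1),
      ann = "phospho-STAT6 dimerization"),
    r("mass_action_irreversible", 2, reactants = c(pSTAT6d_c = 1),
      products = c(pSTAT6d_n = 1), ann = "STAT6 dimer nuclear import"),
    r("mass_action_irreversible", 0.6, reactants = c(pSTAT6d_n = 1),
      products = c(STAT6c = 2),
      ann = "nuclear dephosphorylation and export"),
    r("mass_action_reversible", c(1e-4, 0.5),
      reactants = c(pSTAT1d_n = 1, pSTAT6d_n = 1),
      products = c(S1S6_n = 1),
      ann = "mutual sequestration: STAT6 suppresses STAT1 activity"),
    ## M2 transcription factors and markers -------------------------------
    r("hill_activation", c(900, 300), products = c(IRF4 = 1),
      modifiers = "pSTAT6d_n", ann = "STAT6-driven IRF-4 expression"),
    r("mass_action_irreversible", 0.4, reactants = c(IRF4 = 1),
      ann = "IRF-4 degradation"),
    r("hill_activation", c(600, 300), products = c(PPARg = 1),
      modifiers = "pSTAT6d_n", ann = "STAT6-driven PPAR-gamma expression"),
    r("mass_action_irreversible", 0.25, reactants = c(PPARg = 1),
      ann = "PPAR-gamma degradation"),
    r("hill_activation", c(200, 1000), num = 99,
      products = c(Arg1_mRNA = 1), modifiers = "IRF4",
      ann = "IRF-4 driven Arg-1 transcription"),
    r("hill_activation", c(60, 100), products = c(Arg1_mRNA = 1),
      modifiers = "HIF2_n", ann = "HIF-2 driven Arg-1 transcription"),
    r("mass_action_irreversible", 1, reactants = c(Arg1_mRNA = 1),
      ann = "Arg-1 transcript decay"),
    r("mass_action_irreversible", 10, products = c(Arg1 = 1),
      modifiers = "Arg1_mRNA", ann = "Arg-1 translation"),
    r("mass_action_irreversible", 0.3, reactants = c(Arg1 = 1),
      ann = "Arg-1 degradation"),
    r("hill_activation", c(600, 10000), num = 78,
      products = c(IL10_c = 1), modifiers = "pAKT",
      ann = "AKT-dependent IL-10 synthesis"),
    r("mass_action_irreversible", 2, reactants = c(IL10_c = 1),
      products = c(IL10 = 1), ann = "IL-10 secretion"),
    r("mass_action_irreversible", 0.2, reactants = c(IL10 = 1),
      ann = "secreted IL-10 clearance"),
    r("hill_activation", c(600, 100), products = c(VEGF_c = 1),
      modifiers = "HIF2_n", ann = "HIF-driven VEGF synthesis"),
    r("mass_action_irreversible", 2, reactants = c(VEGF_c = 1),
      products = c(VEGF = 1), ann = "VEGF secretion"),
    r("mass_action_irreversible", 0.2, reactants = c(VEGF = 1),
      ann = "secreted VEGF clearance"))
}

#' The integrated macrophage polarization model
#'
#' Builds the full reaction network coupling the IFN-gamma/STAT1/IRF-1 (M1),
#' IL-4/STAT6/AKT (M2) and oxygen/HIF pathways, with SOCS1/3 negative
#' feedback, STAT1-STAT6 mutual antagonism, miR-93 and miR-3473b
#' post-transcriptional regulation, and the IRG-1/itaconate/ROS metabolic
#' axis. The network comprises 80 nodes drawn from 34 unique species groups
#' connected by 130 reactions.
#'
#' This is a synthetic transcription of the published pathway description:
#' the topology follows the literature mechanisms the model text describes,
#' but the kinetic constants and copy numbers are this package's own
#' nominal, synthetic parameter set. They give a stable unpolarized
#' baseline and qualitatively correct stimulus responses, and are the
#' reference point for perturbation presets, sensitivity ranges and
#' calibration demonstrations; they are not literature-fitted values.
#'
#' Default marker panels: M1 = iNOS, TNF-alpha, IL-12, CXCL9, CXCL10
#' (mRNA level) and IFN-gamma; M2 = Arg-1, IL-10, VEGF. The panel sizes (6
#' and 3) follow the M1/M2 score definition; membership is configurable in
#' [m1m2_score()] because the score's marker identities are an inference
#' from the figures rather than an explicit list.
#'
#' @return validated `mp_model` with marker panels `m1` and `m2`.
#' @export
macrophage_model <- function() {
  specs <- .macro_reactions()
  fixed <- vapply(specs, function(x) as.integer(x$num %||% NA), 1L)
  free <- setdiff(seq_len(length(specs)), fixed[!is.na(fixed)])
  fi <- 1L
  vals <- numeric(0)
  reactions <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    num <- if (!is.na(fixed[i])) fixed[i] else { n <- free[fi]; fi <- fi + 1L; n }
    labs <- switch(sp$kind,
      mass_action_irreversible = sprintf("k%d", num),
      mass_action_reversible = sprintf(c("kf%d", "kr%d"), num),
      hill_activation = ,
      hill_inhibition = if (length(sp$vals) == 3L)
        sprintf(c("k%d", "ka%d", "n%d"), num) else
        sprintf(c("k%d", "ka%d"), num))
    stopifnot(length(labs) == length(sp$vals))
    vals <- c(vals, setNames(sp$vals, labs))
    reactions[[i]] <- mp_reaction(sprintf("r%03d", num),
                                  reactants = sp$reactants,
                                  products = sp$products,
                                  kind = sp$kind, params = labs,
                                  modifiers = sp$modifiers,
                                  annotation = sp$ann)
  }
  mp_model(.macro_species(), reactions,
           mp_parameters(vals, provenance = "synthetic"),
           marker_panels = list(
             m1 = c("iNOS", "TNFa", "IL12", "CXCL9", "CXCL10", "IFNg"),
             m2 = c("Arg1", "IL10", "VEGF")),
           name = "macrophage_polarization")
}

#' Synthetic copy-number priors for the macrophage model
#'
#' Literature-style copy-number reference values (molecules per cell) for
#' every unique-species group, used by the steady-state admissibility
#' check (0.5x-2x band). These are synthetic reference values consistent
#' with the model's unpolarized baseline, standing in for the global
#' proteome/transcriptome copy-number surveys a literature calibration
#' would use.
#'
#' @return an [mp_prior()] over all 34 groups.
#' @export
macrophage_priors <- function() {
  mp_prior(c(
    STAT1 = 2e5, STAT6 = 2e5, AKT = 1e5, O2 = 2.1e5,
    IFNGR = 2000, IL4R = 2000, IFNg = 500, IL4 = 200,
    IRF1 = 2500, IRF4 = 250, IRF9 = 1200, PPARg = 260,
    SOCS1 = 40, SOCS3 = 75, iNOS = 800, TNFa = 700,
    IL12 = 200, CXCL9 = 200, CXCL10 = 190, Arg1 = 900,
    IL10 = 37, VEGF = 240, miR3473b = 3300, miR93 = 4400,
    PTEN = 6300, IRG1 = 67, ITA = 1300, ROS = 7400,
    HIF1a = 200, HIF2a = 54, HIF1b = 1e4, PHD = 12000,
    HIF1 = 23, HIF2 = 8))
}
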