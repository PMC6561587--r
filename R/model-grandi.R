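# Epicardial human ventricular action-potential model (Grandi-Pasqualini-
# Bers formulation): fast and background Na+ currents, transient outward
# (fast/slow), rapid and slow delayed rectifiers, inward rectifier, plateau
# and Ca2+-activated Cl- currents, L-type Ca2+ current with junctional/
# subsarcolemmal compartmentation, Na+/Ca2+ exchange, Na+/K+ pump,
# sarcolemmal and SR Ca2+ pumps, RyR release, and the full set of Na+/Ca2+
# buffers.  38 state variables besides v; all states live on membrane nodes
# and may vary along the membrane.
#
# State layout (columns):
#  1 m      2 h      3 j      4 d      5 f      6 fcaBj  7 fcaBsl
#  8 xtos   9 ytos  10 xtof  11 ytof  12 xkr   13 xks
# 14 RyRr  15 RyRo  16 RyRi
# 17 NaBj  18 NaBsl
# 19 TnCL  20 TnCHc 21 TnCHm 22 CaM   23 Myoc  24 Myom  25 SRB
# 26 SLLj  27 SLLsl 28 SLHj  29 SLHsl
# 30 Csqnb 31 Ca_sr
# 32 Naj   33 Nasl  34 Nai   35 Ki
# 36 Caj   37 Casl  38 Cai

.grandi_state_names <- c(
  "m", "h", "j", "d", "f", "fcaBj", "fcaBsl",
  "xtos", "ytos", "xtof", "ytof", "xkr", "xks",
  "RyRr", "RyRo", "RyRi", "NaBj", "NaBsl",
  "TnCL", "TnCHc", "TnCHm", "CaM", "Myoc", "Myom", "SRB",
  "SLLj", "SLLsl", "SLHj", "SLHsl",
  "Csqnb", "Ca_sr", "Naj", "Nasl", "Nai", "Ki",
  "Caj", "Casl", "Cai")

# Quiescent initial conditions (epicardial parameter set), equilibrated for
# 20 s of quiescence so the state is self-consistent at rest.
.grandi_y0 <- c(
  m = 3.6907030e-3, h = 6.3086526e-1, j = 6.3088952e-1,
  d = 2.8606273e-6, f = 9.9521524e-1,
  fcaBj = 2.3704338e-2, fcaBsl = 1.4261740e-2,
  xtos = 4.3599169e-4, ytos = 9.9999596e-1,
  xtof = 4.3599266e-4, ytof = 9.9999595e-1,
  xkr = 6.0522538e-7, xks = 4.2409226e-3,
  RyRr = 9.0145274e-1, RyRo = 6.7435730e-7, RyRi = 7.3720513e-8,
  NaBj = 3.5097089, NaBsl = 7.6592607e-1,
  TnCL = 8.5056960e-3, TnCHc = 1.0733323e-1, TnCHm = 1.5477565e-2,
  CaM = 2.8089640e-4, Myoc = 1.2548555e-3, Myom = 1.3824306e-1,
  SRB = 2.0758427e-3,
  SLLj = 7.1573268e-3, SLLsl = 9.3945830e-3,
  SLHj = 7.1952951e-2, SLHsl = 1.0990427e-1,
  Csqnb = 1.1796795, Ca_sr = 5.3987227e-1,
  Naj = 8.6516230, Nasl = 8.6520186, Nai = 8.6522999, Ki = 120,
  Caj = 1.6992246e-4, Casl = 1.0125930e-4, Cai = 8.2897632e-5)

.grandi_v0 <- -81.5868

#' Epicardial human ventricular ionic model
#'
#' Port of the Grandi-Pasqualini-Bers human ventricular action-potential
#' model (epicardial parameter set), the physiological membrane model of the
#' simulator.  The fast sodium conductance may be set per membrane node
#' (non-uniform channel placement); every other current uses the published
#' densities.  The returned `rhs` exposes the fast I_Na separately for the
#' analysis pipeline.
#'
#' @return An `emi_ionic_model` with 38 state variables, resting potential
#'   about -81.5 mV and gbar_Na = 23 mS/cm^2.
#' @export
grandi_epicardial <- function() {
  ## constants
  R <- 8314; Frdy <- 96485; Temp <- 310
  FoRT <- Frdy / (R * Temp)
  Qpow <- (Temp - 310) / 10
  Cmem <- 1.3810e-10  # whole-cell capacitance, F

  ## geometry / compartment volumes (L)
  cellLength <- 100; cellRadius <- 10.25
  Vcell <- pi * cellRadius^2 * cellLength * 1e-15
  Vmyo <- 0.65 * Vcell; Vsr <- 0.035 * Vcell
  Vsl <- 0.02 * Vcell; Vjunc <- 0.0539 * 0.01 * Vcell
  J_ca_juncsl <- 1 / 1.2134e12; J_ca_slmyo <- 1 / 2.68510e11
  J_na_juncsl <- 1 / (1.6382e12 / 3 * 100)
  J_na_slmyo <- 1 / (1.8308e10 / 3 * 100)

  Fjunc <- 0.11; Fsl <- 1 - Fjunc
  Fjunc_CaL <- 0.9; Fsl_CaL <- 0.1

  ## fixed ion concentrations (mM)
  Ko <- 5.4; Nao <- 140; Cao <- 1.8; Cli <- 15; Clo <- 150; Mgi <- 1

  ## Na transport
  GNa <- 23; GNaB <- 0.597e-3
  IbarNaK <- 1.8; KmNaip <- 11; KmKo <- 1.5

  ## K currents
  pNaK <- 0.01833
  gkp <- 2 * 0.001
  gkr <- 0.035 * sqrt(Ko / 5.4)
  gks <- 0.0035
  GtoSlow <- 0.0156; GtoFast <- 0.1144  # epicardial

  ## Cl currents
  GClCa <- 0.5 * 0.109625; GClB <- 9e-3; KdClCa <- 100e-3

  ## I_Ca
  pNa <- 0.50 * 1.5e-8; pCa <- 0.50 * 5.4e-4; pK <- 0.50 * 2.7e-7
  Q10CaL <- 1.8

  ## NCX, pumps, background Ca
  IbarNCX <- 4.5; KmCai <- 3.59e-3; KmCao <- 1.3
  KmNai <- 12.29; KmNao <- 87.5; ksat <- 0.32; nu <- 0.27
  Kdact <- 0.150e-3; Q10NCX <- 1.57
  IbarSLCaP <- 0.0673; KmPCa <- 0.5e-3; Q10SLCaP <- 2.35
  GCaB <- 5.513e-4

  ## SR fluxes
  Q10SRCaP <- 2.6; Vmax_SRCaP <- 5.3114e-3
  Kmf <- 0.246e-3; Kmr <- 1.7; hillSRCaP <- 1.787
  ks <- 25; koCa <- 10; kom <- 0.06; kiCa <- 0.5; kim <- 0.005
  ec50SR <- 0.45; MaxSR <- 15; MinSR <- 1

  ## buffering
  Bmax_Naj <- 7.561; Bmax_Nasl <- 1.65
  koff_na <- 1e-3; kon_na <- 0.1e-3
  Bmax_TnClow <- 70e-3; koff_tncl <- 19.6e-3; kon_tncl <- 32.7
  Bmax_TnChigh <- 140e-3
  koff_tnchca <- 0.032e-3; kon_tnchca <- 2.37
  koff_tnchmg <- 3.33e-3; kon_tnchmg <- 3e-3
  Bmax_CaM <- 24e-3; koff_cam <- 238e-3; kon_cam <- 34
  Bmax_myosin <- 140e-3
  koff_myoca <- 0.46e-3; kon_myoca <- 13.8
  koff_myomg <- 0.057e-3; kon_myomg <- 0.0157
  Bmax_SR <- 19 * 0.9e-3; koff_sr <- 60e-3; kon_sr <- 100
  Bmax_SLlowsl <- 37.4e-3 * Vmyo / Vsl
  Bmax_SLlowj <- 4.6e-3 * Vmyo / Vjunc * 0.1
  koff_sll <- 1300e-3; kon_sll <- 100
  Bmax_SLhighsl <- 13.4e-3 * Vmyo / Vsl
  Bmax_SLhighj <- 1.65e-3 * Vmyo / Vjunc * 0.1
  koff_slh <- 30e-3; kon_slh <- 100
  Bmax_Csqn <- 140e-3 * Vmyo / Vsr
  koff_csqn <- 65; kon_csqn <- 100

  init <- function(n) {
    matrix(.grandi_y0, nrow = n, ncol = length(.grandi_y0), byrow = TRUE,
           dimnames = list(NULL, .grandi_state_names))
  }

  rhs <- function(v, S, gna) {
    m <- S[, 1]; h <- S[, 2]; j <- S[, 3]
    d <- S[, 4]; f <- S[, 5]; fcaBj <- S[, 6]; fcaBsl <- S[, 7]
    xtos <- S[, 8]; ytos <- S[, 9]; xtof <- S[, 10]; ytof <- S[, 11]
    xkr <- S[, 12]; xks <- S[, 13]
    RyRr <- S[, 14]; RyRo <- S[, 15]; RyRi <- S[, 16]
    NaBj <- S[, 17]; NaBsl <- S[, 18]
    TnCL <- S[, 19]; TnCHc <- S[, 20]; TnCHm <- S[, 21]
    CaM <- S[, 22]; Myoc <- S[, 23]; Myom <- S[, 24]; SRB <- S[, 25]
    SLLj <- S[, 26]; SLLsl <- S[, 27]; SLHj <- S[, 28]; SLHsl <- S[, 29]
    Csqnb <- S[, 30]; Ca_sr <- S[, 31]
    Naj <- S[, 32]; Nasl <- S[, 33]; Nai <- S[, 34]; Ki <- S[, 35]
    Caj <- S[, 36]; Casl <- S[, 37]; Cai <- S[, 38]

    ## Nernst potentials
    ena_junc <- (1 / FoRT) * log(Nao / Naj)
    ena_sl <- (1 / FoRT) * log(Nao / Nasl)
    ek <- (1 / FoRT) * log(Ko / Ki)
    eca_junc <- (1 / FoRT / 2) * log(Cao / Caj)
    eca_sl <- (1 / FoRT / 2) * log(Cao / Casl)
    ecl <- (1 / FoRT) * log(Cli / Clo)

    ## fast I_Na
    mss <- 1 / (1 + exp(-(56.86 + v) / 9.03))^2
    taum <- 0.1292 * exp(-((v + 45.79) / 15.54)^2) +
      0.06487 * exp(-((v - 4.823) / 51.12)^2)
    lo <- v < -40
    ah <- ifelse(lo, 0.057 * exp(-(v + 80) / 6.8), 0)
    bh <- ifelse(lo, 2.7 * exp(0.079 * v) + 3.1e5 * exp(0.3485 * v),
                 0.77 / (0.13 * (1 + exp(-(v + 10.66) / 11.1))))
    tauh <- 1 / (ah + bh)
    hss <- 1 / (1 + exp((v + 71.55) / 7.43))^2
    aj <- ifelse(lo,
                 (-2.5428e4 * exp(0.2444 * v) - 6.948e-6 * exp(-0.04391 * v)) *
                   (v + 37.78) / (1 + exp(0.311 * (v + 79.23))),
                 0)
    bj <- ifelse(lo,
                 0.02424 * exp(-0.01052 * v) /
                   (1 + exp(-0.1378 * (v + 40.14))),
                 0.6 * exp(0.057 * v) / (1 + exp(-0.1 * (v + 32))))
    tauj <- 1 / (aj + bj)
    jss <- 1 / (1 + exp((v + 71.55) / 7.43))^2
    I_Na_junc <- Fjunc * gna * m^3 * h * j * (v - ena_junc)
    I_Na_sl <- Fsl * gna * m^3 * h * j * (v - ena_sl)
    I_Na <- I_Na_junc + I_Na_sl

    ## background Na
    I_nabk_junc <- Fjunc * GNaB * (v - ena_junc)
    I_nabk_sl <- Fsl * GNaB * (v - ena_sl)

    ## Na/K pump
    sigma <- (exp(Nao / 67.3) - 1) / 7
    fnak <- 1 / (1 + 0.1245 * exp(-0.1 * v * FoRT) +
                   0.0365 * sigma * exp(-v * FoRT))
    I_nak_junc <- Fjunc * IbarNaK * fnak * Ko /
      (1 + (KmNaip / Naj)^4) / (Ko + KmKo)
    I_nak_sl <- Fsl * IbarNaK * fnak * Ko /
      (1 + (KmNaip / Nasl)^4) / (Ko + KmKo)
    I_nak <- I_nak_junc + I_nak_sl

    ## I_Kr
    xrss <- 1 / (1 + exp(-(v + 10) / 5))
    tauxr <- 550 / (1 + exp((-22 - v) / 9)) * 6 / (1 + exp((v + 11) / 9)) +
      230 / (1 + exp((v + 40) / 20))
    rkr <- 1 / (1 + exp((v + 74) / 24))
    I_kr <- gkr * xkr * rkr * (v - ek)

    ## I_Ks
    eks <- (1 / FoRT) * log((Ko + pNaK * Nao) / (Ki + pNaK * Nai))
    xsss <- 1 / (1 + exp(-(v + 3.8) / 14.25))
    tauxs <- 990.1 / (1 + exp(-(v + 2.436) / 14.12))
    I_ks <- gks * xks^2 * (v - eks)

    ## I_Kp
    kp_kp <- 1 / (1 + exp(7.488 - v / 5.98))
    I_kp <- gkp * kp_kp * (v - ek)

    ## I_to (epicardial: large fast component)
    xtoss <- 1 / (1 + exp(-(v - 19.0) / 13))
    ytoss <- 1 / (1 + exp((v + 19.5) / 5))
    tauxtos <- 9 / (1 + exp((v + 3.0) / 15)) + 0.5
    tauytos <- 800 / (1 + exp((v + 60.0) / 10)) + 30
    I_tos <- GtoSlow * xtos * ytos * (v - ek)
    tauxtof <- 8.5 * exp(-((v + 45) / 50)^2) + 0.5
    tauytof <- 85 * exp(-((v + 40)^2 / 220)) + 7
    I_tof <- GtoFast * xtof * ytof * (v - ek)
    I_to <- I_tos + I_tof

    ## I_K1
    aki <- 1.02 / (1 + exp(0.2385 * (v - ek - 59.215)))
    bki <- (0.49124 * exp(0.08032 * (v + 5.476 - ek)) +
              exp(0.06175 * (v - ek - 594.31))) /
      (1 + exp(-0.5143 * (v - ek + 4.753)))
    kiss <- aki / (aki + bki)
    I_k1 <- 0.35 * sqrt(Ko / 5.4) * kiss * (v - ek)

    ## Ca-activated and background Cl
    I_ClCa <- GClCa / (1 + KdClCa / Caj) * Fjunc * (v - ecl) +
      GClCa / (1 + KdClCa / Casl) * Fsl * (v - ecl)
    I_Clbk <- GClB * (v - ecl)

    ## I_Ca (L-type)
    dss <- 1 / (1 + exp(-(v + 5) / 6))
    u5 <- (v + 5) / 6
    taud <- ifelse(abs(v + 5) < 1e-6,
                   1 / (2 * 0.035 * 6),
                   dss * (1 - exp(-u5)) / (0.035 * (v + 5)))
    fss <- 1 / (1 + exp((v + 35) / 9)) + 0.6 / (1 + exp((50 - v) / 20))
    tauf <- 1 / (0.0197 * exp(-(0.0337 * (v + 14.5))^2) + 0.02)
    dfcaBj <- 1.7 * Caj * (1 - fcaBj) - 11.9e-3 * fcaBj
    dfcaBsl <- 1.7 * Casl * (1 - fcaBsl) - 11.9e-3 * fcaBsl
    vf <- v * FoRT
    vg <- ifelse(abs(v) < 1e-6, 1e-6, v)  # removable GHK singularity at 0
    vgf <- vg * FoRT
    ex2 <- exp(2 * vgf); ex1 <- exp(vgf)
    ibarca_j <- pCa * 4 * (vg * Frdy * FoRT) *
      (0.341 * Caj * ex2 - 0.341 * Cao) / (ex2 - 1)
    ibarca_sl <- pCa * 4 * (vg * Frdy * FoRT) *
      (0.341 * Casl * ex2 - 0.341 * Cao) / (ex2 - 1)
    ibark <- pK * (vg * Frdy * FoRT) *
      (0.75 * Ki * ex1 - 0.75 * Ko) / (ex1 - 1)
    ibarna_j <- pNa * (vg * Frdy * FoRT) *
      (0.75 * Naj * ex1 - 0.75 * Nao) / (ex1 - 1)
    ibarna_sl <- pNa * (vg * Frdy * FoRT) *
      (0.75 * Nasl * ex1 - 0.75 * Nao) / (ex1 - 1)
    QQ <- Q10CaL^Qpow
    I_Ca_junc <- Fjunc_CaL * ibarca_j * d * f * (1 - fcaBj) * QQ * 0.45
    I_Ca_sl <- Fsl_CaL * ibarca_sl * d * f * (1 - fcaBsl) * QQ * 0.45
    I_CaK <- ibark * d * f *
      (Fjunc_CaL * (1 - fcaBj) + Fsl_CaL * (1 - fcaBsl)) * QQ * 0.45
    I_CaNa_junc <- Fjunc_CaL * ibarna_j * d * f * (1 - fcaBj) * QQ * 0.45
    I_CaNa_sl <- Fsl_CaL * ibarna_sl * d * f * (1 - fcaBsl) * QQ * 0.45

    ## Na/Ca exchanger
    Ka_junc <- 1 / (1 + (Kdact / Caj)^2)
    Ka_sl <- 1 / (1 + (Kdact / Casl)^2)
    s1_junc <- exp(nu * vf) * Naj^3 * Cao
    s1_sl <- exp(nu * vf) * Nasl^3 * Cao
    s2_junc <- exp((nu - 1) * vf) * Nao^3 * Caj
    s2_sl <- exp((nu - 1) * vf) * Nao^3 * Casl
    s3_junc <- KmCai * Nao^3 * (1 + (Naj / KmNai)^3) +
      KmNao^3 * Caj * (1 + Caj / KmCai) + KmCao * Naj^3 +
      Naj^3 * Cao + Nao^3 * Caj
    s3_sl <- KmCai * Nao^3 * (1 + (Nasl / KmNai)^3) +
      KmNao^3 * Casl * (1 + Casl / KmCai) + KmCao * Nasl^3 +
      Nasl^3 * Cao + Nao^3 * Casl
    QN <- Q10NCX^Qpow
    I_ncx_junc <- Fjunc * IbarNCX * QN * Ka_junc * (s1_junc - s2_junc) /
      s3_junc / (1 + ksat * exp((nu - 1) * vf))
    I_ncx_sl <- Fsl * IbarNCX * QN * Ka_sl * (s1_sl - s2_sl) /
      s3_sl / (1 + ksat * exp((nu - 1) * vf))

    ## sarcolemmal Ca pump and background Ca
    QP <- Q10SLCaP^Qpow
    I_pca_junc <- Fjunc * QP * IbarSLCaP * Caj^1.6 / (KmPCa^1.6 + Caj^1.6)
    I_pca_sl <- Fsl * QP * IbarSLCaP * Casl^1.6 / (KmPCa^1.6 + Casl^1.6)
    I_cabk_junc <- Fjunc * GCaB * (v - eca_junc)
    I_cabk_sl <- Fsl * GCaB * (v - eca_sl)

    ## SR: release, uptake, leak
    kCaSR <- MaxSR - (MaxSR - MinSR) / (1 + (ec50SR / Ca_sr)^2.5)
    koSRCa <- koCa / kCaSR
    kiSRCa <- kiCa * kCaSR
    RI <- 1 - RyRr - RyRo - RyRi
    dRyRr <- (kim * RI - kiSRCa * Caj * RyRr) -
      (koSRCa * Caj^2 * RyRr - kom * RyRo)
    dRyRo <- (koSRCa * Caj^2 * RyRr - kom * RyRo) -
      (kiSRCa * Caj * RyRo - kim * RyRi)
    dRyRi <- (kiSRCa * Caj * RyRo - kim * RyRi) -
      (kom * RyRi - koSRCa * Caj^2 * RI)
    J_SRCarel <- ks * RyRo * (Ca_sr - Caj)
    QS <- Q10SRCaP^Qpow
    J_serca <- QS * Vmax_SRCaP *
      ((Cai / Kmf)^hillSRCaP - (Ca_sr / Kmr)^hillSRCaP) /
      (1 + (Cai / Kmf)^hillSRCaP + (Ca_sr / Kmr)^hillSRCaP)
    J_SRleak <- 5.348e-6 * (Ca_sr - Caj)

    ## Na buffers
    dNaBj <- kon_na * Naj * (Bmax_Naj - NaBj) - koff_na * NaBj
    dNaBsl <- kon_na * Nasl * (Bmax_Nasl - NaBsl) - koff_na * NaBsl

    ## cytosolic Ca buffers
    dTnCL <- kon_tncl * Cai * (Bmax_TnClow - TnCL) - koff_tncl * TnCL
    dTnCHc <- kon_tnchca * Cai * (Bmax_TnChigh - TnCHc - TnCHm) -
      koff_tnchca * TnCHc
    dTnCHm <- kon_tnchmg * Mgi * (Bmax_TnChigh - TnCHc - TnCHm) -
      koff_tnchmg * TnCHm
    dCaM <- kon_cam * Cai * (Bmax_CaM - CaM) - koff_cam * CaM
    dMyoc <- kon_myoca * Cai * (Bmax_myosin - Myoc - Myom) -
      koff_myoca * Myoc
    dMyom <- kon_myomg * Mgi * (Bmax_myosin - Myoc - Myom) -
      koff_myomg * Myom
    dSRB <- kon_sr * Cai * (Bmax_SR - SRB) - koff_sr * SRB
    J_CaB_cytosol <- dTnCL + dTnCHc + dTnCHm + dCaM + dMyoc + dMyom + dSRB

    ## junctional / SL Ca buffers
    dSLLj <- kon_sll * Caj * (Bmax_SLlowj - SLLj) - koff_sll * SLLj
    dSLLsl <- kon_sll * Casl * (Bmax_SLlowsl - SLLsl) - koff_sll * SLLsl
    dSLHj <- kon_slh * Caj * (Bmax_SLhighj - SLHj) - koff_slh * SLHj
    dSLHsl <- kon_slh * Casl * (Bmax_SLhighsl - SLHsl) - koff_slh * SLHsl
    J_CaB_junction <- dSLLj + dSLHj
    J_CaB_sl <- dSLLsl + dSLHsl

    ## SR Ca and Csqn
    dCsqnb <- kon_csqn * Ca_sr * (Bmax_Csqn - Csqnb) - koff_csqn * Csqnb
    dCa_sr <- J_serca - (J_SRleak * Vmyo / Vsr + J_SRCarel) - dCsqnb

    ## Na concentrations
    I_Na_tot_junc <- I_Na_junc + I_nabk_junc + 3 * I_ncx_junc +
      3 * I_nak_junc + I_CaNa_junc
    I_Na_tot_sl <- I_Na_sl + I_nabk_sl + 3 * I_ncx_sl + 3 * I_nak_sl +
      I_CaNa_sl
    dNaj <- -I_Na_tot_junc * Cmem / (Vjunc * Frdy) +
      J_na_juncsl / Vjunc * (Nasl - Naj) - dNaBj
    dNasl <- -I_Na_tot_sl * Cmem / (Vsl * Frdy) +
      J_na_juncsl / Vsl * (Naj - Nasl) +
      J_na_slmyo / Vsl * (Nai - Nasl) - dNaBsl
    dNai <- J_na_slmyo / Vmyo * (Nasl - Nai)
    dKi <- 0 * v

    ## Ca concentrations
    I_Ca_tot_junc <- I_Ca_junc + I_cabk_junc + I_pca_junc - 2 * I_ncx_junc
    I_Ca_tot_sl <- I_Ca_sl + I_cabk_sl + I_pca_sl - 2 * I_ncx_sl
    dCaj <- -I_Ca_tot_junc * Cmem / (Vjunc * 2 * Frdy) +
      J_ca_juncsl / Vjunc * (Casl - Caj) - J_CaB_junction +
      J_SRCarel * Vsr / Vjunc + J_SRleak * Vmyo / Vjunc
    dCasl <- -I_Ca_tot_sl * Cmem / (Vsl * 2 * Frdy) +
      J_ca_juncsl / Vsl * (Caj - Casl) +
      J_ca_slmyo / Vsl * (Cai - Casl) - J_CaB_sl
    dCai <- -J_serca * Vsr / Vmyo - J_CaB_cytosol +
      J_ca_slmyo / Vmyo * (Casl - Cai)

    ## total membrane current (uA/uF; equals uA/cm^2 at C_m = 1 uF/cm^2)
    I_Na_tot <- I_Na_tot_junc + I_Na_tot_sl
    I_Cl_tot <- I_ClCa + I_Clbk
    I_Ca_tot <- I_Ca_tot_junc + I_Ca_tot_sl
    I_K_tot <- I_to + I_kr + I_ks + I_k1 - 2 * I_nak + I_CaK + I_kp
    I_ion <- I_Na_tot + I_Cl_tot + I_Ca_tot + I_K_tot

    dS <- cbind(
      (mss - m) / taum, (hss - h) / tauh, (jss - j) / tauj,
      (dss - d) / taud, (fss - f) / tauf, dfcaBj, dfcaBsl,
      (xtoss - xtos) / tauxtos, (ytoss - ytos) / tauytos,
      (xtoss - xtof) / tauxtof, (ytoss - ytof) / tauytof,
      (xrss - xkr) / tauxr, (xsss - xks) / tauxs,
      dRyRr, dRyRo, dRyRi, dNaBj, dNaBsl,
      dTnCL, dTnCHc, dTnCHm, dCaM, dMyoc, dMyom, dSRB,
      dSLLj, dSLLsl, dSLHj, dSLHsl,
      dCsqnb, dCa_sr, dNaj, dNasl, dNai, dKi,
      dCaj, dCasl, dCai)

    list(I_ion = I_ion, dS = dS, I_Na = I_Na)
  }

  new_ionic_model("grandi_epicardial", .grandi_state_names, .grandi_v0,
                  23, init, rhs)
}
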