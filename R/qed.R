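# Quantitative estimate of drug-likeness (QED). Eight physicochemical
# properties are mapped through asymmetric double-sigmoid desirability
# functions fitted in the original drug-likeness publication (constants
# below are those published values) and combined as a weighted geometric
# mean. Property inputs: MW, Crippen logP, H-bond acceptors/donors, TPSA,
# rotatable bonds, aromatic rings and the structural-alert count, computed
# as described in descriptors.R / alerts.R.

QED_ADS <- list(
  MW     = c(a = 2.817065973,  b = 392.5754953, c = 290.7489764,
             d = 2.419764353,  e = 49.22325677, f = 65.37051707,
             dmax = 104.9805561),
  ALOGP  = c(a = 3.172690585,  b = 137.8624751, c = 2.534937431,
             d = 4.581497897,  e = 0.822739154, f = 0.576295591,
             dmax = 131.3186604),
  HBA    = c(a = 2.948620388,  b = 160.4605972, c = 3.615294657,
             d = 4.435986202,  e = 0.290141953, f = 1.300669958,
             dmax = 148.7763046),
  HBD    = c(a = 1.618662227,  b = 1010.051101, c = 0.985094388,
             d = 1e-09,        e = 0.713820843, f = 0.920922555,
             dmax = 258.1632616),
  PSA    = c(a = 1.876861559,  b = 125.2232657, c = 62.90773554,
             d = 87.83366614,  e = 12.01999824, f = 28.51324732,
             dmax = 104.5686167),
  ROTB   = c(a = 0.01,         b = 272.4121427, c = 2.55837997,
             d = 1.565547684,  e = 1.271567166, f = 2.758063707,
             dmax = 105.4420403),
  AROM   = c(a = 3.21778897,   b = 957.7374108, c = 2.274627939,
             d = 1e-09,        e = 1.317690384, f = 0.375760881,
             dmax = 312.337261),
  ALERTS = c(a = 0.01,         b = 1199.094025, c = -0.09002883,
             d = 1e-09,        e = 0.185904477, f = 0.875193782,
             dmax = 417.725314)
)

QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                 PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

# asymmetric double sigmoid desirability, normalized to its maximum
qed_ads <- function(x, p) {
  v <- p[["a"]] +
    p[["b"]] / (1 + exp(-(x - p[["c"]] + p[["d"]] / 2) / p[["e"]])) *
    (1 - 1 / (1 + exp(-(x - p[["c"]] - p[["d"]] / 2) / p[["f"]])))
  max(v / p[["dmax"]], 1e-06)
}

# QED from a descriptor panel (see descriptor_panel)
qed_from_panel <- function(panel) {
  props <- c(MW = panel$mw, ALOGP = panel$logp, HBA = panel$hba,
             HBD = panel$hbd, PSA = panel$tpsa, ROTB = panel$n_rotatable,
             AROM = panel$n_aromatic_rings, ALERTS = panel$n_alerts)
  if (anyNA(props)) return(NA_real_)
  d <- vapply(names(QED_ADS),
              function(k) qed_ads(props[[k]], QED_ADS[[k]]), numeric(1))
  exp(sum(QED_WEIGHTS * log(d)) / sum(QED_WEIGHTS))
}
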