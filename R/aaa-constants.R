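# Package-wide constants (file named to sort first in the collate order).

AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALLOWED   <- c(AA_CANONICAL, "X")
DOMAIN_NAMES <- c("CZB", "MCP", "GGDEF", "EAL", "CheW", "TM", "other")

# alpha-3 motif: 1=C, 2=any canonical, 3=L/F, 4=G, 5=any canonical,
# 6=W, 7=Y/L.  X never satisfies a motif position.
MOTIF_REGEX <- paste0("C[", paste(AA_CANONICAL, collapse = ""),
                      "][LF]G[", paste(AA_CANONICAL, collapse = ""),
                      "]W[YL]")

SUBGROUPS <- c("soluble_chemoreceptor", "membrane_chemoreceptor",
               "dgc", "dgc_eal", "eal_czb", "chew_czb", "czb_only")
CHEMO_SUBGROUPS <- c("soluble_chemoreceptor", "membrane_chemoreceptor")
DGC_SUBGROUPS <- c("dgc", "dgc_eal")

# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2, X = 0)

`%||%` <- function(a, b) if (is.null(a)) b else a
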