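#' enzdes: computational active-site design funnel for serine hydrolases
#'
#' Tools for the structure-based redesign funnel used to engineer MHET
#' hydrolases for enzymatic PET recycling: geometric matching of a
#' Ser-His-Asp catalytic motif plus oxyanion hole into protein scaffolds
#' ([matchActiveSite()]), transition-state conformer placement
#' ([generateTSLibrary()]), rotamer-based redesign with certified
#' global-minimum search ([searchGmec()], [enumerateDesigns()],
#' [selectCandidates()]), catalytic-indicator screening of trajectory
#' frames ([catalyticIndicators()], [twoRoundFunnel()]), and downstream
#' kinetics and PET-conversion arithmetic ([fitMichaelisMenten()],
#' [petConversion()], [crystallinity()]). Seeded synthetic-data
#' generators ([makeToyScaffold()], [synthFrames()], [synthKinetics()])
#' make every stage testable without external data.
#'
#' @keywords internal
#' @import methods
#' @importFrom stats optim nls nls.control lm coef median rnorm runif rlnorm setNames complete.cases aggregate
#' @importFrom utils modifyList read.csv
"_PACKAGE"
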