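## Alert rules: ids, levels and explanations.
##
## Four ids mirror the numbering established for the issues this toolkit
## reproduces (007, 012, 977, 978); all toolkit-assigned ids are >= 9000
## to avoid any collision.  Levels: A (serious), B, C (check), G
## (informative).  Level assignment is centralized here so the mapping is
## auditable; grading functions are monotone in the measured value.

.alert_rules <- list(
  `7`    = list(level = "G", expl = "Hydrogen atoms at calculated positions only; do not over-interpret hydrogen-bond geometry."),
  `12`   = list(level = "C", expl = "An embedded payload does not match its declared checksum: the file was corrupted or edited after refinement."),
  `977`  = list(level = "C", expl = "A hydrogen site is not supported by the difference electron density."),
  `978`  = list(level = "G", expl = "Mean difference density at bond midpoints; spherical-atom refinements on good data normally leave positive bonding density here."),
  `9001` = list(level = "C", expl = "The Hall space-group symbol is missing."),
  `9002` = list(level = "C", expl = "The Hermann-Mauguin space-group symbol is missing."),
  `9003` = list(level = "C", expl = "The symmetry-operator loop is missing."),
  `9004` = list(level = "B", expl = "The Hall symbol cannot be expanded."),
  `9005` = list(level = "B", expl = "The symmetry-operator loop cannot be parsed."),
  `9006` = list(level = "B", expl = "Listed operators and the Hall-symbol expansion disagree."),
  `9007` = list(level = "B", expl = "Hermann-Mauguin and Hall symbols disagree for a tabulated setting."),
  `9008` = list(level = "G", expl = "Non-standard setting: the Hermann-Mauguin/Hall comparison was skipped."),
  `9009` = list(level = "B", expl = "The cell metric violates a constraint of the crystal system implied by the operators."),
  `9010` = list(level = "B", expl = "Z (formula units per cell) is missing."),
  `9011` = list(level = "B", expl = "Reported and calculated densities disagree."),
  `9012` = list(level = "B", expl = "The reported sum formula does not match the atom list."),
  `9013` = list(level = "C", expl = "The reported formula weight does not match the formula."),
  `9014` = list(level = "C", expl = "Short intermolecular H...H contact: check calculated hydrogen positions."),
  `9015` = list(level = "B", expl = "Short O...O or O...N contact: a hydrogen atom of a short hydrogen bond may be missing."),
  `9016` = list(level = "G", expl = "Short halogen...halogen interaction (structural feature, not an error)."),
  `9017` = list(level = "C", expl = "Intermolecular contact shorter than the van der Waals sum."),
  `9018` = list(level = "G", expl = "Short contact involves disordered sites: inspect the disorder model."),
  `9019` = list(level = "C", expl = "A connected species has its centre of gravity outside the unit-cell bounds."),
  `9020` = list(level = "C", expl = "The reported transmission range is implausible for the crystal size and composition."),
  `9021` = list(level = "G", expl = "Absorption plausibility not assessed (missing dimensions or wavelength off-table)."),
  `9022` = list(level = "C", expl = "Low ratio of unique observed reflections to refined parameters."),
  `9023` = list(level = "C", expl = "Reported resonant scattering factors deviate from the bundled tables."),
  `9024` = list(level = "G", expl = "Resonant scattering factors not verifiable at this wavelength."),
  `9025` = list(level = "C", expl = "Reported site-symmetry order disagrees with the recomputed value."),
  `9026` = list(level = "C", expl = "Occupancy outside (0, 1]."),
  `9027` = list(level = "C", expl = "Rigid-bond test: displacement amplitudes along a bond differ significantly; check atom-type assignments."),
  `9030` = list(level = "C", expl = "No reflection data available; reflection-based checks skipped."),
  `9031` = list(level = "B", expl = "Recalculated and reported R1 disagree."),
  `9032` = list(level = "B", expl = "Recalculated and reported wR2 disagree."),
  `9033` = list(level = "C", expl = "Recalculated and reported goodness of fit disagree."),
  `9034` = list(level = "C", expl = "Large internal-consistency residual Rint of the unmerged data."),
  `9035` = list(level = "C", expl = "Data completeness below expectation at the 0.6 1/A resolution mark."),
  `9036` = list(level = "B", expl = "Significant intensity on systematically absent reflections: the space-group assignment may be wrong."),
  `9037` = list(level = "C", expl = "Analysis-of-variance bin deviates: scale K or bin goodness of fit off nominal."),
  `9038` = list(level = "C", expl = "Normal-probability plot of weighted residuals deviates from linearity (outliers or a wrong error model)."),
  `9039` = list(level = "B", expl = "Reported uncertainties are an implausibly exact function of intensity: screen for fabricated data."),
  `9040` = list(level = "G", expl = "Absolute-structure (Parsons-style quotient) estimate."),
  `9041` = list(level = "B", expl = "A twin law explains the intensity outliers; refinement with the law should drop R1."),
  `9042` = list(level = "C", expl = "Difference-density extremum beyond the featureless bound."),
  `9043` = list(level = "C", expl = "Large difference density within 1 A of a heavy atom: probable absorption-correction artefact."),
  `9044` = list(level = "B", expl = "Significant difference density on an atom site: possible wrong atom-type assignment."),
  `9045` = list(level = "C", expl = "Reported residual-density extrema disagree with the recalculated map."),
  `9046` = list(level = "C", expl = "Solvent-accessible void in the structure: unmodelled solvent or wrong/missing atoms."),
  `9047` = list(level = "G", expl = "Integrated electron count in a solvent-accessible void."),
  `9048` = list(level = "B", expl = "Coordinates (nearly) conform to additional symmetry: the space group may be of too low symmetry."),
  `9049` = list(level = "G", expl = "Reflection corroboration of a proposed symmetry operation (extinction-violation count under the implied group)."),
  `9050` = list(level = "G", expl = "Embedded payload present but its checksum could not be verified."),
  `9051` = list(level = "G", expl = "No embedded reflection/instruction payloads in the archive."),
  `9052` = list(level = "C", expl = "A validation stage failed internally; its checks were skipped."),
  `9053` = list(level = "C", expl = "A required data item is missing."),
  `9054` = list(level = "G", expl = "Suggested noise cutoff: beyond this resolution the observed fraction drops below threshold.")
)

alert_row <- function(id, message, value = NA_real_, level = NULL) {
  rule <- .alert_rules[[as.character(id)]]
  if (is.null(rule)) stop_ciflint(sprintf("unknown alert id %s", id), "ciflint_alert_error")
  data.frame(id = as.integer(id), level = level %||% rule$level,
             message = message, value = value, stringsAsFactors = FALSE)
}

## monotone grading helpers
.grade_up <- function(value, c_at, b_at, a_at) {
  if (value >= a_at) "A" else if (value >= b_at) "B" else if (value >= c_at) "C" else "pass"
}

#' Alert rule registry
#'
#' @return data.frame of all rule ids with default level and explanation.
#' @export
alert_rules <- function() {
  data.frame(id = as.integer(names(.alert_rules)),
             level = vapply(.alert_rules, `[[`, character(1), "level"),
             explanation = vapply(.alert_rules, `[[`, character(1), "expl"),
             row.names = NULL, stringsAsFactors = FALSE)
}
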