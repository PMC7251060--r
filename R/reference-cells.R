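#' Reference CO activity cell means and SEMs for the 2x2 cohort
#'
#' Published-style group means and standard errors of cytochrome oxidase
#' activity (umol/min/g) for 44 atlas-defined regions of interest in a
#' 2x2 (surgery x drug) rat cohort: sham+saline, sham+MB, 2VO+saline and
#' 2VO+MB (2VO = permanent bilateral common carotid artery occlusion;
#' MB = low-dose methylene blue). These cell moments parameterise the
#' synthetic cohort generator and anchor moment-reconstruction checks of
#' the factorial statistics.
#'
#' @return A data frame with one row per ROI and columns `roi` (full name),
#'   `abbrev`, then `mean_<group>` and `sem_<group>` for the four groups
#'   `sham_saline`, `sham_mb`, `vo_saline`, `vo_mb`.
#' @examples
#' ref <- co_cohort_reference()
#' ref[ref$abbrev == "V2", ]
#' @export
co_cohort_reference <- function() {
  txt <- "
roi|abbrev|m1|s1|m2|s2|m3|s3|m4|s4
Prelimbic cortex|PLC|246.43|9.88|243.80|13.63|225.09|16.21|247.76|9.69
Medial orbital cortex|MO|245.24|11.49|239.99|11.85|221.16|15.31|248.61|9.82
Ventral orbital cortex|VO|254.38|9.57|248.35|12.49|235.53|12.42|254.43|8.99
Lateral orbital cortex|LO|251.27|8.88|249.62|11.52|233.50|11.32|252.09|7.87
Agranular insular cortex|AI|227.63|7.31|220.18|8.90|211.33|10.82|229.76|8.69
Infralimbic cortex|IL|281.87|9.58|270.41|14.29|269.97|15.16|272.44|5.28
Primary motor cortex|M1|237.17|4.92|230.15|10.02|222.54|13.23|232.86|3.74
Secondary motor cortex|M2|242.28|6.10|233.62|10.50|214.49|8.99|243.12|7.61
Primary somatosensory cortex|S1|214.27|13.65|214.25|7.76|222.05|11.91|212.94|7.10
Secondary somatosensory cortex|S2|226.35|7.55|218.51|10.34|210.28|7.41|230.64|8.22
Cingulate cortex|Cin|259.93|8.32|244.58|10.16|258.77|15.84|257.88|9.85
Perirhinal cortex|PRh|230.05|10.87|210.98|8.89|186.46|14.63|223.64|10.99
Primary visual cortex|V1|241.59|10.36|242.43|7.87|201.47|12.24|247.19|9.66
Secondary visual cortex|V2|249.72|11.05|249.49|9.86|206.10|13.52|239.80|7.90
Medial septal nucleus|MS|203.40|8.33|197.97|12.39|202.64|10.36|197.97|6.04
Lateral septal nucleus|LS|272.30|8.28|262.01|12.81|273.92|11.81|268.67|5.58
Acumbens core|AcbC|313.40|9.76|304.24|10.43|315.15|17.36|307.88|7.59
Acumbens shell|AcbS|241.13|10.53|223.67|8.36|233.98|8.35|224.90|7.96
Caudate/Putamen|CPu|198.87|13.32|199.51|8.52|191.14|11.26|191.27|6.12
Globus palidus|GP|115.97|6.57|108.53|4.83|115.23|5.74|112.64|4.92
Ventral pallidum|VP|179.11|5.82|169.26|6.40|168.38|8.74|168.31|4.50
Lateral hypothalamus|LH|160.75|9.32|157.53|9.78|154.51|5.90|163.81|8.06
Paraventricular nucleus|PVH|191.74|6.94|183.50|8.14|184.33|8.43|203.21|6.86
Medial preoptic area|MPO|206.22|6.62|198.81|7.51|210.35|10.84|208.42|5.72
Bed nucleus stria terminalis|BST|233.80|7.98|218.64|9.49|237.61|14.51|224.12|6.61
Subthalamic nucleus|Sub|273.20|6.04|249.10|10.74|249.36|14.37|248.75|10.91
Medial geniculate nucleus|MGN|255.28|8.38|245.48|5.66|240.78|12.86|235.70|5.45
Basomedial amygdala|BMA|186.21|7.73|180.59|10.02|175.09|4.88|195.70|9.16
Medial amygdala|MEA|227.95|10.39|220.31|11.47|194.29|9.88|226.00|9.75
Basolateral amygdala|BLA|268.46|14.51|254.36|14.44|230.77|12.21|266.47|12.53
Central amygdala|CEA|223.13|8.63|219.37|10.03|206.30|9.63|234.55|9.36
Anterior hippocampus CA1|CA1A|213.48|11.42|199.98|8.20|188.32|18.91|213.97|13.79
Anterior hippocampus CA2|CA2A|224.26|13.21|203.44|8.69|195.70|16.03|214.87|11.19
Anterior hippocampus CA3|CA3A|238.88|15.71|213.68|10.05|200.94|15.59|216.38|8.13
Anterior dentate gyrus|DGA|319.76|26.01|294.90|15.21|306.25|31.40|297.03|19.93
Posterior hippocampus CA1|CA1P|298.13|13.98|277.27|12.72|266.56|14.28|277.08|13.51
Posterior hippocampus CA2|CA2P|275.84|11.87|249.69|11.82|236.40|17.96|248.44|10.82
Posterior hippocampus CA3|CA3P|292.89|9.91|272.22|13.02|255.42|16.45|269.08|9.99
Posterior dentate gyrus|DGP|269.60|15.75|256.92|10.66|258.72|12.20|255.88|7.02
Subiculum|S|239.98|12.04|226.65|10.53|221.74|11.20|217.73|6.72
Superior colliculus|SC|254.18|13.53|246.46|8.80|240.89|10.46|249.47|8.05
Substantia nigra|SN|214.80|8.68|207.29|8.24|211.66|11.57|209.81|6.72
Red nucleus|R|250.37|12.02|251.90|13.05|234.69|13.86|257.29|12.34
Ventral tegmental area|VTA|97.29|1.32|99.91|5.86|88.06|3.55|96.05|5.11"
  df <- read.table(text = txt, sep = "|", header = TRUE,
                   stringsAsFactors = FALSE, strip.white = TRUE)
  names(df) <- c("roi", "abbrev",
                 "mean_sham_saline", "sem_sham_saline",
                 "mean_sham_mb", "sem_sham_mb",
                 "mean_vo_saline", "sem_vo_saline",
                 "mean_vo_mb", "sem_vo_mb")
  df
}

#' Canonical group labels of the 2x2 design
#'
#' Order: sham+saline, sham+MB, 2VO+saline, 2VO+MB. The surgery and drug
#' factors are parsed from each label at the `+`.
#' @return Character vector of length 4.
#' @export
co_group_labels <- function() {
  c("sham+saline", "sham+MB", "2VO+saline", "2VO+MB")
}

#' Default anatomical grouping of the 44 ROIs
#'
#' Used for the default block-structured within-group correlation matrix
#' and for mapping lesion overlap onto lesion type labels (neocortical,
#' striatal, hippocampal, perirhinal).
#'
#' @return Named list of character vectors of ROI abbreviations.
#' @export
co_roi_groups <- function() {
  list(
    prefrontal   = c("PLC", "MO", "VO", "LO", "AI", "IL"),
    neocortical  = c("M1", "M2", "S1", "S2", "Cin", "V1", "V2"),
    visual       = c("V1", "V2", "SC"),
    hippocampal  = c("CA1A", "CA2A", "CA3A", "DGA",
                     "CA1P", "CA2P", "CA3P", "DGP", "S"),
    amygdala     = c("BMA", "MEA", "BLA", "CEA"),
    striatal     = c("CPu"),
    perirhinal   = c("PRh")
  )
}

# Parse "sham+saline"-style labels into surgery/drug factors.
parse_group_labels <- function(labels) {
  parts <- strsplit(labels, "+", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("group labels must be of the form '<surgery>+<drug>': ",
         paste(labels[bad], collapse = ", "))
  }
  data.frame(group = labels,
             surgery = vapply(parts, `[[`, "", 1L),
             drug = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}
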