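# Builds the frozen synthetic stand-in network packaged as
# inst/extdata/default_network.csv.
#
# Targets (aggregates of the exemplar network of noninsulin glucose-lowering
# drug trials): 161 trials, 24 drugs, 7 ATC level-5 classes, 210,046
# participants; right-skewed trials-per-drug (several single-trial drugs, a
# few drugs with 15+ trials); right-skewed enrollments, minimum 300, with a
# heavy tail for cardiovascular-outcome-sized trials; taspoglutide carried by
# a single small trial. Run once; the CSV is versioned, not regenerated at
# build time.

drugs <- data.frame(
  drug_code = c("A10BA02",
                "A10BB07", "A10BB09", "A10BB12",
                "A10BG02", "A10BG03",
                "A10BH01", "A10BH02", "A10BH03", "A10BH04", "A10BH05",
                "A10BH06",
                "A10BJ01", "A10BJ02", "A10BJ03", "A10BJ04", "A10BJ05",
                "A10BJ06", "A10BJ07",
                "A10BK01", "A10BK02", "A10BK03", "A10BK04",
                "A10BX02"),
  drug_name = c("metformin",
                "glipizide", "gliclazide", "glimepiride",
                "rosiglitazone", "pioglitazone",
                "sitagliptin", "vildagliptin", "saxagliptin", "alogliptin",
                "linagliptin", "gemigliptin",
                "exenatide", "liraglutide", "lixisenatide", "albiglutide",
                "dulaglutide", "semaglutide", "taspoglutide",
                "dapagliflozin", "canagliflozin", "empagliflozin",
                "ertugliflozin",
                "repaglinide"),
  n_trials = c(11,
               1, 2, 3,
               6, 8,
               16, 9, 8, 6, 8, 2,
               9, 14, 4, 4, 8, 7, 1,
               10, 9, 10, 3,
               2),
  stringsAsFactors = FALSE
)
drugs$class_code <- substr(drugs$drug_code, 1, 5)
stopifnot(sum(drugs$n_trials) == 161, nrow(drugs) == 24,
          length(unique(drugs$class_code)) == 7)

set.seed(20210818)
rows <- do.call(rbind, lapply(seq_len(nrow(drugs)), function(i) {
  k <- drugs$n_trials[i]
  # single-trial drugs get small trials (the regime where pooling matters);
  # multi-trial programmes get a log-normal spread with a heavy tail
  enroll <- if (k == 1) round(runif(1, 300, 450)) else
    pmax(round(rlnorm(k, meanlog = 6.6, sdlog = 0.9)), 300)
  data.frame(drug_code = drugs$drug_code[i], drug_name = drugs$drug_name[i],
             class_code = drugs$class_code[i], enrollment = enroll,
             stringsAsFactors = FALSE)
}))

# a few cardiovascular-outcome-scale trials for the big programmes
big <- c("A10BJ02", "A10BK03", "A10BH01", "A10BK02", "A10BH03", "A10BJ06")
for (dg in big) {
  idx <- which(rows$drug_code == dg)
  rows$enrollment[idx[which.max(rows$enrollment[idx])]] <-
    round(runif(1, 7000, 15000))
}

# rescale to the exact participant total, respecting the 300 floor
target <- 210046
small <- rows$enrollment <= 450 & ave(rows$enrollment, rows$drug_code,
                                      FUN = length) == 1
f <- (target - sum(rows$enrollment[small])) / sum(rows$enrollment[!small])
rows$enrollment[!small] <- pmax(round(rows$enrollment[!small] * f), 300)
rows$enrollment[which.max(rows$enrollment)] <-
  rows$enrollment[which.max(rows$enrollment)] + (target - sum(rows$enrollment))

rows <- rows[order(rows$class_code, rows$drug_code, -rows$enrollment), ]
rows$trial_id <- sprintf("TRIAL%03d", seq_len(nrow(rows)))
rows <- rows[, c("trial_id", "drug_code", "drug_name", "class_code",
                 "enrollment")]
stopifnot(nrow(rows) == 161, sum(rows$enrollment) == target,
          min(rows$enrollment) >= 300)

write.csv(rows, file.path("inst", "extdata", "default_network.csv"),
          row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
cat("wrote", nrow(rows), "trials, total", sum(rows$enrollment), "\n")
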