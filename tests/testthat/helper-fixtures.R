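# fixtures are built in code; tiny CSVs are written to tempdir

writeTempCsv <- function(df, name = "tab.csv") {
  path <- file.path(tempfile("fix"), name)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

# minimal single-site-year phenotype table: nLines x nReps plots, one trial
tinyPheno <- function(nLines = 4, nReps = 2, cycle = "2013-14",
                      treatment = "Optimal Bed", gy = NULL, seed = 1) {
  set.seed(seed)
  lines <- sprintf("L%02d", seq_len(nLines))
  df <- expand.grid(line_id = lines, replicate = seq_len(nReps),
                    stringsAsFactors = FALSE)
  df$plot_id <- sprintf("P%03d", seq_len(nrow(df)))
  df$cycle <- cycle
  df$treatment <- treatment
  df$trial <- 1L
  df$block <- 1L
  df$gy <- if (is.null(gy)) round(runif(nrow(df), 2, 6), 3) else gy
  df$lodging <- 0
  df$dthd <- ifelse(df$replicate == 1, 75 + seq_len(nrow(df)) %% 5, NA)
  df$dtmt <- df$dthd + 35
  df[c("plot_id", "line_id", "cycle", "treatment", "trial", "replicate",
       "block", "gy", "lodging", "dthd", "dtmt")]
}

# small simulated dataset shared by several test files (lazy, cached)
smallSimCache <- new.env()
smallSim <- function(seed = 42) {
  key <- paste0("s", seed)
  if (is.null(smallSimCache[[key]])) {
    cfg <- makeScenario("baseline", nFamilies = 25, sibsPerFamily = 2,
                        nFounders = 20, nMarkers = 300,
                        cycles = c("2013-14", "2014-15"),
                        treatments = c("Optimal Bed", "Severe Drought"),
                        linesPerTrial = 18, masterSeed = seed)
    smallSimCache[[key]] <- suppressMessages(simulateDataset(cfg))
  }
  smallSimCache[[key]]
}

# dense brute-force Henderson MME solve, independent of the package solver
denseMME <- function(y, X, Zs, Ks, s2, s2e) {
  V <- diag(s2e, length(y))
  for (m in seq_along(Zs)) V <- V + s2[m] * Zs[[m]] %*% Ks[[m]] %*% t(Zs[[m]])
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  u <- lapply(seq_along(Zs), function(m)
    s2[m] * Ks[[m]] %*% t(Zs[[m]]) %*% Vi %*% r)
  yhat <- as.numeric(X %*% beta + Reduce(`+`, lapply(seq_along(Zs),
    function(m) Zs[[m]] %*% u[[m]])))
  list(beta = as.numeric(beta), u = u, yhat = yhat)
}
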