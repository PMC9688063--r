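mkRec <- function(X, fs = 250) {
  mont <- standardMontage1020()
  X <- X[seq_len(min(nrow(X), 19)), , drop = FALSE]
  if (nrow(X) < 19) {
    mont <- montage(mont@channels[seq_len(nrow(X))],
                    mont@positions[seq_len(nrow(X)), , drop = FALSE])
  }
  rownames(X) <- mont@channels
  new("EEGRecording", data = X, fs = fs, montage = mont,
      subjectId = "T", group = "HC")
}

test_that("band-pass keeps in-band tones and attenuates out-of-band tones", {
  fs <- 250
  t <- (0:(10 * fs - 1)) / fs
  ampAt <- function(x, f) {
    sp <- abs(fft(x)) / length(x)
    2 * sp[round(f * length(x) / fs) + 1]
  }
  for (f0 in c(10, 50)) {
    X <- rbind(sin(2 * pi * f0 * t), -sin(2 * pi * f0 * t))
    out <- recordingData(bandpassFilter(mkRec(X), 2, 20))
    ratio <- ampAt(out[1, ], f0) / ampAt(X[1, ], f0)
    if (f0 == 10) expect_gt(20 * log10(ratio), -1)   # <= 1 dB change
    else expect_lt(20 * log10(ratio), -20)           # >= 20 dB attenuation
  }
  z <- matrix(0, 2, 500)
  expect_equal(recordingData(bandpassFilter(mkRec(z))), z,
               ignore_attr = TRUE)
  expect_error(bandpassFilter(mkRec(z), 2, 130), "Nyquist")
})

test_that("average reference zeroes column means and is idempotent", {
  set.seed(1)
  X <- matrix(rnorm(19 * 100), 19)
  r1 <- averageReference(mkRec(X))
  expect_lt(max(abs(colMeans(recordingData(r1)))), 1e-12)
  expect_equal(recordingData(averageReference(r1)), recordingData(r1),
               tolerance = 1e-12)
  withOffset <- averageReference(mkRec(X + 42))
  expect_equal(recordingData(withOffset), recordingData(r1),
               tolerance = 1e-9)
  expect_error(averageReference(mkRec(X[1, , drop = FALSE])), "2 channels")
})

test_that("filtering and referencing commute", {
  set.seed(2)
  X <- matrix(rnorm(19 * 1000), 19)
  a <- recordingData(averageReference(bandpassFilter(mkRec(X))))
  b <- recordingData(bandpassFilter(averageReference(mkRec(X))))
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("epoching cuts floor(duration/length) epochs and is lossless", {
  set.seed(3)
  X <- matrix(rnorm(2 * 900 * 250), 2)
  es <- epochSignal(mkRec(X), 5)
  expect_identical(nEpochs(es), 180L)
  expect_identical(dim(es@epochs)[3], 1250L)
  X12 <- X[, 1:(12 * 250), drop = FALSE]
  es12 <- epochSignal(mkRec(X12), 5)
  expect_identical(nEpochs(es12), 2L)
  recon <- cbind(epochData(es12, 1), epochData(es12, 2))
  expect_equal(recon, X12[, 1:2500], ignore_attr = TRUE)
  expect_identical(nEpochs(epochSignal(mkRec(X[, 1:1250]), 5)), 1L)
  expect_error(epochSignal(mkRec(X[, 1:1000]), 5), "shorter")
})

test_that("variance rejection flags exactly the inflated epoch", {
  set.seed(4)
  X <- matrix(rnorm(2 * 100 * 250), 2)
  X[, (41 * 250 + 1):(42 * 250)] <- X[, (41 * 250 + 1):(42 * 250)] * 10
  es <- rejectOutlierEpochs(epochSignal(mkRec(X), 1))
  expect_identical(which(!retainedMask(es)), 42L)
  # identical epochs: SD = 0, none rejected
  Xc <- matrix(rep(rnorm(2 * 250), 10), 2)
  esc <- rejectOutlierEpochs(epochSignal(mkRec(Xc), 1))
  expect_true(all(retainedMask(esc)))
  expect_identical(sum(retainedMask(es)) + sum(!retainedMask(es)),
                   nEpochs(es))
  expect_error(rejectOutlierEpochs(epochSignal(mkRec(X[, 1:500]), 1)),
               "3 epochs")
})
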