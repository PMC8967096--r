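"""Reference Gaussian-HMM fit used as an independent cross-check.

Reads a JSON job file:
  {"data_csv": path, "A": [[...]], "pi": [...], "Sigma": [[[...]]],
   "n_iter": int, "out": path}

Fits a full-covariance Gaussian HMM from exactly that initialization with
the means pinned at zero (the embedded LFP is z-normalized, so the
implementation under test uses zero-mean emissions), runs `n_iter` EM
iterations without early stopping, and writes the final log-likelihood.
"""
import json
import sys

import numpy as np
from hmmlearn.hmm import GaussianHMM


def main(job_path):
    with open(job_path) as fh:
        job = json.load(fh)
    X = np.loadtxt(job["data_csv"], delimiter=",", ndmin=2)
    A = np.asarray(job["A"], dtype=float)
    pi = np.asarray(job["pi"], dtype=float)
    Sigma = np.asarray(job["Sigma"], dtype=float)  # K x d x d
    K, d = Sigma.shape[0], Sigma.shape[2]

    # 'm' must be in params for hmmlearn to accumulate the posterior stats
    # its covariance M-step divides by; the means are pinned at zero through
    # an overwhelming MAP prior, so the model is the same zero-mean Gaussian
    # HMM as the implementation under test.
    m = GaussianHMM(n_components=K, covariance_type="full",
                    n_iter=int(job["n_iter"]), tol=-np.inf,
                    init_params="", params="stmc", min_covar=0.0,
                    means_prior=np.zeros((K, d)), means_weight=1e12)
    m.startprob_ = pi
    m.transmat_ = A
    m.means_ = np.zeros((K, d))
    m.covars_ = Sigma
    m.fit(X)
    out = {"loglik": float(m.score(X)),
           "monitor": [float(v) for v in m.monitor_.history]}
    with open(job["out"], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1])
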