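"""Convert an Axon ABF current-clamp file to the neutral sweep-set CSV
exchange format (CSV + JSON sidecar) understood by read_sweepset().

Usage: python abf2sweep.py input.abf output.csv
"""
import json
import sys

import numpy as np
import pyabf


def main(src, dst):
    abf = pyabf.ABF(src)
    volts = []
    currents = []
    for i in abf.sweepList:
        abf.setSweep(i)
        volts.append(np.asarray(abf.sweepY, dtype=float))
        # mode of the command waveform during the sweep = step current
        cmd = np.asarray(abf.sweepC, dtype=float)
        vals, counts = np.unique(cmd, return_counts=True)
        nonzero = vals[vals != 0]
        currents.append(float(nonzero[0]) if nonzero.size else 0.0)
    t_ms = np.asarray(abf.sweepX, dtype=float) * 1000.0
    # step window from the command epochs of the last sweep
    on = np.flatnonzero(cmd != 0)
    step = [float(t_ms[on[0]]), float(t_ms[on[-1] + 1] if on[-1] + 1 < t_ms.size else t_ms[-1])] \
        if on.size else [float(t_ms[0]), float(t_ms[-1])]
    header = ["time_ms"] + ["sweep_%03d" % (i + 1) for i in range(len(volts))]
    data = np.column_stack([t_ms] + volts)
    np.savetxt(dst, data, delimiter=",", header=",".join(header), comments="",
               fmt="%.17g")
    with open(dst + ".json", "w") as fh:
        json.dump({"format": "v1phys_sweepset", "version": 1,
                   "sampling_rate_hz": float(abf.dataRate),
                   "step_window_ms": step,
                   "current_pA": currents}, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
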