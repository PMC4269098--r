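# Real-network edge lists (not redistributed)

The acceptance test for the published compression figures expects the
public Alon-lab transcription-network edge lists here:

- `yeast.txt`     — yeast transcription network (688 nodes; compresses to
                    345 nodes / 615 edges, 343 parity nodes removed)
- `coliInter.txt` — E. coli transcription network (256 nodes retained)

These files are freely available online but are not bundled; without them
the corresponding test reports an explanatory failure. Lines starting with
`#` are comments; only the first two whitespace-separated tokens per line
(source, target) are used; self-loops (autoregulation) must be removed
before compression, as the incidence representation cannot express them.
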