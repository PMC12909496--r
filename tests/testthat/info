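INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 25 promoter record(s) written to /tmp/RtmpllXIAX/det1/run1.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 25 promoter record(s) written to /tmp/RtmpllXIAX/det1/run2.csv
INFO: 3 promoter record(s) written to /tmp/RtmpllXIAX/def2000/promoters.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 25 promoter record(s) written to /tmp/RtmpRWQzdk/det1/run1.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 25 promoter record(s) written to /tmp/RtmpRWQzdk/det1/run2.csv
INFO: 3 promoter record(s) written to /tmp/RtmpRWQzdk/def2000/promoters.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 25 promoter record(s) written to /tmp/RtmprvwECi/det1/run1.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 25 promoter record(s) written to /tmp/RtmprvwECi/det1/run2.csv
INFO: 3 promoter record(s) written to /tmp/RtmprvwECi/def2000/promoters.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 25 promoter record(s) written to /tmp/RtmpTW5EwT/det1/run1.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 25 promoter record(s) written to /tmp/RtmpTW5EwT/det1/run2.csv
INFO: 3 promoter record(s) written to /tmp/RtmpTW5EwT/def2000/promoters.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 25 promoter record(s) written to /tmp/RtmpLQv1jr/det1/run1.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 25 promoter record(s) written to /tmp/RtmpLQv1jr/det1/run2.csv
INFO: 3 promoter record(s) written to /tmp/RtmpLQv1jr/def2000/promoters.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 25 promoter record(s) written to /tmp/RtmpoPtup8/det1/run1.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 25 promoter record(s) written to /tmp/RtmpoPtup8/det1/run2.csv
INFO: 3 promoter record(s) written to /tmp/RtmpoPtup8/def2000/promoters.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 25 promoter record(s) written to /tmp/RtmpHs4Dlh/det1/run1.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 25 promoter record(s) written to /tmp/RtmpHs4Dlh/det1/run2.csv
INFO: 3 promoter record(s) written to /tmp/RtmpHs4Dlh/def2000/promoters.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 25 promoter record(s) written to /tmp/RtmpHCVgu2/det1/run1.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 25 promoter record(s) written to /tmp/RtmpHCVgu2/det1/run2.csv
INFO: 3 promoter record(s) written to /tmp/RtmpHCVgu2/def2000/promoters.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 20 promoter record(s) written to /tmp/RtmpHCVgu2/fxcli/promoters.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 20 promoter record(s) written to /tmp/RtmpHCVgu2/fxcli/promoters.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 25 promoter record(s) written to /tmp/RtmpuBzxNX/det1/run1.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 25 promoter record(s) written to /tmp/RtmpuBzxNX/det1/run2.csv
INFO: 3 promoter record(s) written to /tmp/RtmpuBzxNX/def2000/promoters.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 20 promoter record(s) written to /tmp/RtmpuBzxNX/fxcli/promoters.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 20 promoter record(s) written to /tmp/RtmpuBzxNX/fxcli/promoters.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 25 promoter record(s) written to /tmp/RtmpQDGw9A/det1/run1.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 25 promoter record(s) written to /tmp/RtmpQDGw9A/det1/run2.csv
INFO: 3 promoter record(s) written to /tmp/RtmpQDGw9A/def2000/promoters.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 20 promoter record(s) written to /tmp/RtmpQDGw9A/fxcli/promoters.csv
INFO: 1 flank window(s) skipped at chromosome boundaries
INFO: 20 promoter record(s) written to /tmp/RtmpQDGw9A/fxcli/promoters.csv
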