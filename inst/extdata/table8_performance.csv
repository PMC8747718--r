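dataset,model,condition,metric,value
PV,N1,data,macro_recall,87.76
PV,N1,data,macro_precision,86.58
PV,N1,data,macro_f1,86.57
PV,N1,data,mean_accuracy,99.16
PV,N1,ad1,macro_recall,89.50
PV,N1,ad1,macro_precision,89.31
PV,N1,ad1,macro_f1,89.26
PV,N1,ad1,mean_accuracy,99.33
PV,N1,ad2,macro_recall,99.45
PV,N1,ad2,macro_precision,99.45
PV,N1,ad2,macro_f1,99.45
PV,N1,ad2,mean_accuracy,99.97
PV,N2,data,macro_recall,92.35
PV,N2,data,macro_precision,92.03
PV,N2,data,macro_f1,91.95
PV,N2,data,mean_accuracy,99.50
PV,N2,ad1,macro_recall,91.54
PV,N2,ad1,macro_precision,90.83
PV,N2,ad1,macro_f1,90.83
PV,N2,ad1,mean_accuracy,99.43
PV,N2,ad2,macro_recall,99.65
PV,N2,ad2,macro_precision,99.65
PV,N2,ad2,macro_f1,99.65
PV,N2,ad2,mean_accuracy,99.98
PV,N3,data,macro_recall,90.20
PV,N3,data,macro_precision,89.61
PV,N3,data,macro_f1,89.57
PV,N3,data,mean_accuracy,99.35
PV,N3,ad1,macro_recall,90.32
PV,N3,ad1,macro_precision,89.80
PV,N3,ad1,macro_f1,89.71
PV,N3,ad1,mean_accuracy,99.36
PV,N3,ad2,macro_recall,99.55
PV,N3,ad2,macro_precision,99.55
PV,N3,ad2,macro_f1,99.55
PV,N3,ad2,mean_accuracy,99.97
PV,AlexNet,data,macro_recall,98.60
PV,AlexNet,data,macro_precision,98.53
PV,AlexNet,data,macro_f1,98.52
PV,AlexNet,data,mean_accuracy,99.91
PV,AlexNet,ad1,macro_recall,98.99
PV,AlexNet,ad1,macro_precision,98.98
PV,AlexNet,ad1,macro_f1,98.98
PV,AlexNet,ad1,mean_accuracy,99.94
PV,AlexNet,ad2,macro_recall,99.74
PV,AlexNet,ad2,macro_precision,99.73
PV,AlexNet,ad2,macro_f1,99.73
PV,AlexNet,ad2,mean_accuracy,99.98
Flavia,N1,data,macro_recall,94.54
Flavia,N1,data,macro_precision,94.30
Flavia,N1,data,macro_f1,94.30
Flavia,N1,data,mean_accuracy,99.64
Flavia,N1,ad1,macro_recall,86.43
Flavia,N1,ad1,macro_precision,85.63
Flavia,N1,ad1,macro_f1,85.45
Flavia,N1,ad1,mean_accuracy,99.10
Flavia,N1,ad2,macro_recall,99.18
Flavia,N1,ad2,macro_precision,99.17
Flavia,N1,ad2,macro_f1,99.17
Flavia,N1,ad2,mean_accuracy,99.95
Flavia,N2,data,macro_recall,96.05
Flavia,N2,data,macro_precision,95.91
Flavia,N2,data,macro_f1,95.91
Flavia,N2,data,mean_accuracy,99.74
Flavia,N2,ad1,macro_recall,90.49
Flavia,N2,ad1,macro_precision,89.77
Flavia,N2,ad1,macro_f1,89.76
Flavia,N2,ad1,mean_accuracy,99.36
Flavia,N2,ad2,macro_recall,99.59
Flavia,N2,ad2,macro_precision,99.59
Flavia,N2,ad2,macro_f1,99.59
Flavia,N2,ad2,mean_accuracy,99.97
Flavia,N3,data,macro_recall,93.99
Flavia,N3,data,macro_precision,93.83
Flavia,N3,data,macro_f1,93.80
Flavia,N3,data,mean_accuracy,99.61
Flavia,N3,ad1,macro_recall,88.49
Flavia,N3,ad1,macro_precision,87.99
Flavia,N3,ad1,macro_f1,87.76
Flavia,N3,ad1,mean_accuracy,99.25
Flavia,N3,ad2,macro_recall,99.37
Flavia,N3,ad2,macro_precision,99.36
Flavia,N3,ad2,macro_f1,99.36
Flavia,N3,ad2,mean_accuracy,99.96
Flavia,AlexNet,data,macro_recall,99.50
Flavia,AlexNet,data,macro_precision,99.48
Flavia,AlexNet,data,macro_f1,99.48
Flavia,AlexNet,data,mean_accuracy,99.97
Flavia,AlexNet,ad1,macro_recall,99.02
Flavia,AlexNet,ad1,macro_precision,98.93
Flavia,AlexNet,ad1,macro_f1,98.93
Flavia,AlexNet,ad1,mean_accuracy,99.93
Flavia,AlexNet,ad2,macro_recall,99.87
Flavia,AlexNet,ad2,macro_precision,99.87
Flavia,AlexNet,ad2,macro_f1,99.87
Flavia,AlexNet,ad2,mean_accuracy,99.99
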