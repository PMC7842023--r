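table,method,tp,fp,fn,tn,acc,spe,sen,pre
proposed,Bi-LSTM,752,115,248,885,0.819,0.885,0.752,0.867
proposed,DBN,710,266,290,734,0.722,0.734,0.710,0.728
proposed,PSR-CNN,935,102,65,898,0.917,0.898,0.935,0.902
proposed,FF-CNN,953,94,47,906,0.929,0.906,0.953,0.910
proposed,FF-CNN-SAM,949,89,51,911,0.930,0.911,0.949,0.914
proposed,FF-CNN-CBAM,959,65,41,935,0.947,0.935,0.959,0.937
classical_features,SVM,645,278,355,722,0.684,0.722,0.645,0.699
classical_features,NB,454,141,546,859,0.657,0.859,0.454,0.763
classical_features,BAT,780,214,220,786,0.783,0.786,0.780,0.785
classical_features,RF,858,221,142,779,0.819,0.779,0.858,0.795
classical_features,DT,746,231,254,769,0.758,0.769,0.746,0.764
energy_features,SVM,796,70,204,930,0.863,0.930,0.796,0.919
energy_features,NB,749,125,251,875,0.812,0.875,0.749,0.857
energy_features,BAT,845,93,155,907,0.876,0.907,0.845,0.901
energy_features,RF,846,32,154,968,0.907,0.968,0.846,0.964
energy_features,DT,879,100,121,900,0.889,0.900,0.879,0.898
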